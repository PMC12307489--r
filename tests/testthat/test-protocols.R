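# Within-subject and leave-one-subject-out protocols on miniature studies.

test_that("within-subject protocol trains one model per subject", {
  study <- tiny_study(n_subjects = 2, n_trials_per_class = 3, seed = 31)
  rep <- within_subject_protocol(study, tiny_config(),
                                 tiny_train(epochs = 2, seed = 3))
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_subject), 2L)
  expect_equal(rep$per_subject$subject, names(study))
  models <- attr(rep, "models")
  expect_equal(length(models), 2L)
  # independent models: different parameters
  expect_false(identical(models[[1]]$params, models[[2]]$params))
  # report means equal hand means; SD matches the two-subject closed form
  expect_equal(rep$mean_accuracy, mean(rep$per_subject$accuracy))
  expect_equal(rep$mean_kappa, mean(rep$per_subject$kappa))
  expect_equal(rep$sd_accuracy,
               abs(diff(rep$per_subject$accuracy)) / sqrt(2))
  expect_output(print(rep), "mean accuracy")
})

test_that("single-subject reports omit the across-subject SD", {
  study <- tiny_study(n_subjects = 1, n_trials_per_class = 3, seed = 37)
  rep <- within_subject_protocol(study, tiny_config(),
                                 tiny_train(epochs = 1, seed = 3))
  expect_true(is.na(rep$sd_accuracy))
})

test_that("missing sessions are reported by subject name", {
  study <- tiny_study(n_subjects = 2, n_trials_per_class = 2, seed = 41)
  broken <- study
  broken$S02$E <- NULL
  expect_error(within_subject_protocol(broken, tiny_config(), tiny_train()),
               "S02")
})

test_that("cross-subject pools hold exactly the other subjects' trials", {
  study <- tiny_study(n_subjects = 3, n_trials_per_class = 2, seed = 43)
  rep <- cross_subject_protocol(study, tiny_config(),
                                tiny_train(epochs = 1, seed = 5))
  pools <- attr(rep, "pool_sizes")
  trials <- vapply(study, function(s) dim(s$T$data)[1], numeric(1))
  for (s in names(study))
    expect_equal(pools[[s]], sum(trials[names(trials) != s]))
  expect_equal(nrow(rep$per_subject), 3L)
  # two subjects: each model trains on exactly the other's training set
  study2 <- study[1:2]
  rep2 <- cross_subject_protocol(study2, tiny_config(),
                                 tiny_train(epochs = 1, seed = 5))
  expect_equal(unname(attr(rep2, "pool_sizes")), unname(rev(trials[1:2])))
  expect_error(cross_subject_protocol(study[1], tiny_config(), tiny_train()),
               ">= 2 subjects")
})

test_that("the ablation runner covers the requested variants", {
  study <- tiny_study(n_subjects = 1, n_trials_per_class = 3, seed = 47)
  tab <- run_ablation(study, variants = c("bi_dense", "hafusenet"),
                      scale = "desk", train = tiny_train(epochs = 1, seed = 7),
                      downsample = 30L, stem_depth = 4L, stem_kernel = 3L,
                      bottleneck_kernel = 3L, branch_kernels = c(3L, 5L),
                      branch_depth = 2L, spatial_out = 6L, pool = 5L,
                      hidden = 8L, fusion_kernel = 3L, fusion_depth = 8L,
                      fc_hidden = 0L, r2c_depth = 4L)
  expect_equal(tab$variant, c("bi_dense", "hafusenet"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})

test_that("configurations round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    model = list(scale = "desk", hidden = 12L, use_scot = FALSE),
    train = list(epochs = 7L, batch_size = 8L, seed = 3L),
    synth = list(n_subjects = 2L, n_trials_per_class = 4L, seed = 9L)), path)
  cfgs <- read_config_yaml(path)
  expect_equal(cfgs$model$hidden, 12L)
  expect_false(cfgs$model$use_scot)
  expect_equal(cfgs$train$epochs, 7L)
  expect_equal(cfgs$synth$n_trials_per_class, 4L)
})
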