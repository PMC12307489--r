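# Metrics (accuracy / kappa / SD / cross-entropy) and the training loop.

test_that("cross-entropy matches its closed forms", {
  expect_equal(cross_entropy(c(1, 0, 0, 0), 0L), 0)
  expect_equal(cross_entropy(rep(0.25, 4), 2L), log(4), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.5, 0.2, 0.2, 0.1), 0L), log(2),
               tolerance = 1e-12)
  # matrix form averages over trials
  pm <- rbind(rep(0.25, 4), c(0.5, 0.3, 0.1, 0.1))
  expect_equal(cross_entropy(pm, c(1L, 0L)), mean(c(log(4), log(2))),
               tolerance = 1e-12)
  # zero probability at the true class is clamped, not infinite
  expect_true(is.finite(cross_entropy(c(0, 1, 0, 0), 0L)))
})

test_that("kappa matches hand evaluation and an independent implementation", {
  cm <- matrix(c(40, 20, 10, 30), 2, 2) # rows truth, cols prediction
  # P0 = 0.7, Pe = 0.5 -> kappa = 0.4
  expect_equal(kappa_score(cm), 0.4, tolerance = 1e-12)
  expect_equal(kappa_score(diag(c(7, 5, 3, 9))), 1)
  # invariant under simultaneous permutation of class labels
  set.seed(2)
  cm4 <- matrix(rpois(16, 20), 4, 4)
  perm <- c(3, 1, 4, 2)
  expect_equal(kappa_score(cm4), kappa_score(cm4[perm, perm]),
               tolerance = 1e-12)
  # cross-check against e1071's classAgreement on random tables
  for (s in 1:5) {
    set.seed(s)
    cmr <- matrix(rpois(16, 15), 4, 4)
    expect_equal(kappa_score(cmr), e1071::classAgreement(cmr)$kappa,
                 tolerance = 1e-10)
  }
  # degenerate all-one-class agreement: Pe = 1 with P0 = 1 returns 1
  cm1 <- matrix(0, 2, 2); cm1[1, 1] <- 10
  expect_equal(kappa_score(cm1), 1)
})

test_that("independent predictions with matched marginals give kappa near 0", {
  set.seed(99)
  ks <- replicate(200, {
    truth <- sample(0:3, 200, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
    pred <- sample(truth) # same marginals, independent of truth
    kappa_score(confusion_matrix(truth, pred))
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("accuracy SD is the sample standard deviation across subjects", {
  expect_equal(accuracy_sd(c(70, 80, 90)), 10)
  expect_equal(accuracy_sd(c(0.5, 0.5, 0.5)), 0)
  a <- 0.62; b <- 0.81
  expect_equal(accuracy_sd(c(a, b)), abs(a - b) / sqrt(2), tolerance = 1e-12)
  expect_error(accuracy_sd(0.7), "at least 2")
})

test_that("training descends, records history, and is seed-reproducible", {
  study <- tiny_study(n_subjects = 1, n_trials_per_class = 8, seed = 17,
                      attenuation = 0.15, noise_sd = 1)
  ep <- study$S01$T
  cfg <- tiny_config(downsample = 15L)
  tr <- tiny_train(epochs = 12, seed = 21)
  fit1 <- hafusenet(ep, config = cfg, train = tr)
  expect_equal(nrow(fit1$history), 12L)
  # descent on a learnable set: late-epoch loss below early-epoch loss
  expect_lt(mean(tail(fit1$history$loss, 3)), mean(fit1$history$loss[1:3]))
  fit2 <- hafusenet(ep, config = cfg, train = tr)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  # a different seed gives a different trajectory
  fit3 <- hafusenet(ep, config = cfg, train = tiny_train(epochs = 12, seed = 22))
  expect_false(identical(fit1$history$loss, fit3$history$loss))
})

test_that("model object methods behave like standard fitted models", {
  study <- tiny_study(n_subjects = 1, n_trials_per_class = 4, seed = 23)
  fit <- hafusenet(study$S01$T, config = tiny_config(),
                   train = tiny_train(epochs = 2, seed = 2))
  expect_s3_class(fit, "hafusenet")
  expect_output(print(fit), "HA-FuseNet")
  expect_output(summary(fit), "history")
  pr <- predict(fit, study$S01$E)
  expect_equal(dim(pr), c(16L, 4L))
  expect_close(rowSums(pr), rep(1, 16), 1e-10)
  cl <- predict(fit, study$S01$E, type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), c("left", "right", "feet", "tongue"))
  expect_true(is.list(coef(fit)) && length(coef(fit)) > 10)
  ev <- evaluate_model(fit, study$S01$E)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(sum(ev$confusion), 16)
  path <- tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("a validation split is carved out when requested", {
  study <- tiny_study(n_subjects = 1, n_trials_per_class = 6, seed = 29)
  fit <- hafusenet(study$S01$T, config = tiny_config(),
                   train = tiny_train(epochs = 2, seed = 2,
                                      val_fraction = 0.25))
  expect_true("val_accuracy" %in% names(fit$history))
})
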