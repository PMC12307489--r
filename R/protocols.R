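# Evaluation protocols: within-subject (one model per subject, trained on the
# subject's T session and tested on its E session) and cross-subject
# (leave-one-subject-out: for subject i the training pool is the union of all
# other subjects' T sessions, the test set is subject i's E session).

check_study <- function(study) {
  for (s in names(study)) {
    if (is.null(study[[s]]$T))
      stop("subject ", s, " is missing the training session (T)")
    if (is.null(study[[s]]$E))
      stop("subject ", s, " is missing the evaluation session (E)")
  }
  invisible(study)
}

#' Within-subject evaluation protocol
#'
#' Trains one independent model per subject on that subject's training-session
#' epochs and evaluates on the same subject's evaluation session; reports
#' per-subject accuracy and kappa, their means, and the across-subject
#' standard deviation of accuracy (absent with a single subject).
#'
#' @param study named list, one entry per subject, each a list with
#'   [epoch_set]s `$T` (train) and `$E` (test) -- see [generate_study()].
#' @param config a [hafusenet_config()].
#' @param train a [train_config()]; each subject's model gets a distinct
#'   sub-seed derived from `train$seed`.
#' @return a [metrics_report()]; fitted models in `attr(, "models")`.
#' @export
within_subject_protocol <- function(study, config = hafusenet_config(),
                                    train = train_config()) {
  check_study(study)
  rows <- list(); cms <- list(); models <- list()
  for (i in seq_along(study)) {
    s <- names(study)[i]
    tcfg <- train
    tcfg$seed <- sub_seed(train$seed, 100L + i)
    fit <- hafusenet(study[[s]]$T, config = config, train = tcfg)
    ev <- evaluate_model(fit, study[[s]]$E)
    rows[[s]] <- data.frame(subject = s, accuracy = ev$accuracy,
                            kappa = ev$kappa)
    cms[[s]] <- ev$confusion
    models[[s]] <- fit
  }
  rep <- metrics_report(do.call(rbind, rows), cms)
  attr(rep, "models") <- models
  rep
}

#' Cross-subject (leave-one-subject-out) evaluation protocol
#'
#' For every subject i the training set is the union of all other subjects'
#' training sessions and the test set is subject i's evaluation session.
#'
#' @inheritParams within_subject_protocol
#' @return a [metrics_report()]; per-subject training-pool sizes in
#'   `attr(, "pool_sizes")`.
#' @export
cross_subject_protocol <- function(study, config = hafusenet_config(),
                                   train = train_config()) {
  check_study(study)
  if (length(study) < 2) stop("cross-subject protocol requires >= 2 subjects")
  rows <- list(); cms <- list(); pools <- integer(0)
  for (i in seq_along(study)) {
    s <- names(study)[i]
    pool <- combine_epochs(lapply(study[-i], `[[`, "T"))
    pools[s] <- dim(pool$data)[1]
    tcfg <- train
    tcfg$seed <- sub_seed(train$seed, 200L + i)
    fit <- hafusenet(pool, config = config, train = tcfg)
    ev <- evaluate_model(fit, study[[s]]$E)
    rows[[s]] <- data.frame(subject = s, accuracy = ev$accuracy,
                            kappa = ev$kappa)
    cms[[s]] <- ev$confusion
  }
  rep <- metrics_report(do.call(rbind, rows), cms)
  attr(rep, "pool_sizes") <- pools
  rep
}

#' Pooled synthetic benchmark at desk scale
#'
#' The package's standard synthetic evaluation: generate one training-session
#' recording per subject, split each subject's trials into train and held-out
#' parts (stratified by class), pool across subjects, train one model, and
#' evaluate on the pooled held-out trials. With the default 9 subjects x 80
#' trials and a `"desk"`-scale model this runs in minutes on one CPU; with
#' `attenuation = 1` the recordings carry no class information and accuracy
#' should sit at the 25% chance level.
#'
#' @param attenuation ERD attenuation factor applied to all four class
#'   profiles (0.3 = clearly separable, 1 = signal-free).
#' @param seed master seed (generator, split, initialization, batching).
#' @param config a [hafusenet_config()].
#' @param train a [train_config()].
#' @param n_subjects,n_trials_per_class study size.
#' @param test_per_class held-out trials per class and subject.
#' @param noise_sd background noise scale, microvolts.
#' @return list with `accuracy`, `kappa`, `confusion`, `n_train`, `n_test`,
#'   the fitted `model`, and the training `history`.
#' @export
synthetic_benchmark <- function(attenuation = 0.3, seed = 1L,
                                config = hafusenet_config("desk"),
                                train = train_config(epochs = 40L,
                                                     batch_size = 32L,
                                                     seed = seed),
                                n_subjects = 9L, n_trials_per_class = 20L,
                                test_per_class = 12L, noise_sd = 2) {
  profs <- synth_config()$class_profiles
  for (i in seq_along(profs)) profs[[i]]$attenuation <- attenuation
  scfg <- synth_config(n_subjects = n_subjects,
                       n_trials_per_class = n_trials_per_class,
                       class_profiles = profs, noise_sd = noise_sd,
                       seed = seed)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  tr <- list(); te <- list()
  set.seed(sub_seed(seed, 7L))
  for (s in subjects) {
    ep <- generate_epochset(scfg, s, "T")
    idx_te <- unlist(lapply(0:(length(profs) - 1L), function(k)
      sample(which(ep$labels == k), test_per_class)))
    idx_tr <- setdiff(seq_along(ep$labels), idx_te)
    sub <- function(idx) epoch_set(ep$data[idx, , , drop = FALSE],
                                   ep$labels[idx], s, ep$session, ep$fs,
                                   ep$window)
    tr[[s]] <- sub(idx_tr)
    te[[s]] <- sub(idx_te)
  }
  train_set <- combine_epochs(tr)
  test_set <- combine_epochs(te)
  train$seed <- seed
  fit <- hafusenet(train_set, config = config, train = train)
  ev <- evaluate_model(fit, test_set)
  list(accuracy = ev$accuracy, kappa = ev$kappa, confusion = ev$confusion,
       n_train = dim(train_set$data)[1], n_test = dim(test_set$data)[1],
       model = fit, history = fit$history)
}

#' Run the ablation family
#'
#' Trains and evaluates each requested ablation variant (see
#' [hafusenet_variant()]) under the within-subject protocol and returns one
#' summary row per variant.
#'
#' @param study as in [within_subject_protocol()].
#' @param variants character vector of variant names.
#' @param scale config scale passed to [hafusenet_variant()].
#' @param train a [train_config()].
#' @param ... further config overrides.
#' @return data.frame with columns `variant`, `accuracy`, `kappa`, `sd`.
#' @export
run_ablation <- function(study, variants = c("inception", "base_inception",
                                             "bi_dense", "di_svse",
                                             "dis_lstm", "hafusenet"),
                         scale = "desk", train = train_config(), ...) {
  rows <- lapply(variants, function(v) {
    cfg <- hafusenet_variant(v, scale = scale, ...)
    rep <- within_subject_protocol(study, cfg, train)
    data.frame(variant = v, accuracy = rep$mean_accuracy,
               kappa = rep$mean_kappa, sd = rep$sd_accuracy)
  })
  do.call(rbind, rows)
}
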