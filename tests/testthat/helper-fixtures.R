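# Shared fixtures: tiny tensors, tiny model/training configurations sized for
# sub-second fits, and small synthetic studies.

rand4 <- function(b, d, c, t, seed = 1) {
  set.seed(seed)
  array(rnorm(b * d * c * t), c(b, d, c, t))
}

rand3 <- function(d, c, t, seed = 1) {
  set.seed(seed)
  array(rnorm(d * c * t), c(d, c, t))
}

# very small network: a few hundred parameters, trains in seconds
tiny_config <- function(...) {
  hafusenet_config("desk",
                   downsample = 30L, stem_depth = 4L, stem_kernel = 3L,
                   bottleneck_expansion = 2L, bottleneck_kernel = 3L,
                   branch_kernels = c(3L, 5L), branch_depth = 2L,
                   spatial_out = 6L, pool = 5L, hidden = 8L,
                   fusion_kernel = 3L, fusion_depth = 8L, fc_hidden = 0L,
                   r2c_depth = 4L, ...)
}

tiny_train <- function(epochs = 2L, seed = 1L, ...) {
  train_config(batch_size = 16L, epochs = epochs, seed = seed, ...)
}

tiny_study <- function(n_subjects = 2L, n_trials_per_class = 3L, seed = 11L,
                       attenuation = 0.3, noise_sd = 2) {
  profs <- synth_config()$class_profiles
  for (i in seq_along(profs)) profs[[i]]$attenuation <- attenuation
  cfg <- synth_config(n_subjects = n_subjects,
                      n_trials_per_class = n_trials_per_class,
                      class_profiles = profs, noise_sd = noise_sd, seed = seed)
  generate_study(cfg)
}

# stratified split of one epoch_set into train/test
split_epochs <- function(ep, n_test_per_class = 5L, seed = 1L) {
  set.seed(seed)
  idx_te <- unlist(lapply(0:3, function(k)
    sample(which(ep$labels == k), n_test_per_class)))
  idx_tr <- setdiff(seq_along(ep$labels), idx_te)
  sub <- function(idx) epoch_set(ep$data[idx, , , drop = FALSE],
                                 ep$labels[idx], ep$subject_id, ep$session,
                                 ep$fs, ep$window)
  list(train = sub(idx_tr), test = sub(idx_te))
}

# plain-R reference for a same-padded depthwise 1 x k temporal convolution
ref_dwconv <- function(x, w, bias = NULL) {
  d <- dim(x)
  k <- ncol(w)
  pad <- (k - 1) %/% 2
  out <- array(0, dim = d)
  for (b in seq_len(d[1])) for (dd in seq_len(d[2])) for (cc in seq_len(d[3]))
    for (tt in seq_len(d[4])) {
      acc <- 0
      for (j in seq_len(k)) {
        tin <- tt + j - 1 - pad
        if (tin >= 1 && tin <= d[4]) acc <- acc + w[dd, j] * x[b, dd, cc, tin]
      }
      out[b, dd, cc, tt] <- acc + if (is.null(bias)) 0 else bias[dd]
    }
  out
}

# band power of a single channel via the periodogram (independent oracle)
band_power <- function(v, fs, lo, hi) {
  n <- length(v)
  sp <- Mod(stats::fft(v - mean(v)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= lo & freqs <= hi
  sum(sp[sel])
}

expect_close <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
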