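# LS-Net, the C2R/R2C adapters and branch fusion.

# plain-R single-layer LSTM reference (gate order i, f, g, o)
ref_lstm <- function(x, wx, wh, b) {
  cin <- nrow(x); T <- ncol(x); H <- ncol(wx) / 4
  h <- rep(0, H); cc <- rep(0, H)
  out <- matrix(0, H, T)
  sig <- function(v) 1 / (1 + exp(-v))
  for (t in seq_len(T)) {
    g <- as.vector(x[, t] %*% wx) + as.vector(h %*% wh) + b
    i <- sig(g[1:H]); f <- sig(g[H + 1:H])
    gg <- tanh(g[2 * H + 1:H]); o <- sig(g[3 * H + 1:H])
    cc <- f * cc + i * gg
    h <- o * tanh(cc)
    out[, t] <- h
  }
  out
}

test_that("a single LSTM layer matches the hand-unrolled recurrence", {
  set.seed(3)
  x <- matrix(rnorm(4 * 3), 4, 3) # C = 4, T = 3
  y <- lsnet_forward(x, n_layers = 1, hidden = 2, use_scot = FALSE, seed = 5)
  p <- attr(y, "params")
  ref <- ref_lstm(x, p[["ls.l1.wx"]], p[["ls.l1.wh"]], as.vector(p[["ls.l1.b"]]))
  expect_close(y, ref, 1e-12)
  expect_equal(dim(y), c(2, 3))
})

test_that("zero input yields the SCoT image of the bias-driven trajectory", {
  x <- matrix(0, 4, 3)
  y <- lsnet_forward(x, n_layers = 1, hidden = 2, use_scot = TRUE, seed = 6)
  p <- attr(y, "params")
  traj <- ref_lstm(x, p[["ls.l1.wx"]], p[["ls.l1.wh"]], as.vector(p[["ls.l1.b"]]))
  scot_p <- local({
    sel <- names(p)[startsWith(names(p), "ls.scot1.")]
    stats::setNames(p[sel], sub("^ls\\.scot1\\.", "scot.", sel))
  })
  ref <- scot_apply(array(traj, c(1, 2, 3)), allow_depth1 = TRUE,
                    params = scot_p)
  expect_close(y, array(ref, c(2, 3)), 1e-10)
})

test_that("LS-Net output is (H, T) for any input geometry", {
  for (ct in list(c(22, 75), c(5, 40))) {
    x <- matrix(rnorm(ct[1] * ct[2]), ct[1], ct[2])
    y <- lsnet_forward(x, n_layers = 2, hidden = 7, seed = 2)
    expect_equal(dim(y), c(7, ct[2]))
  }
})

test_that("C2R merges depth x channel and projects per time step", {
  f <- rand3(8, 22, 30, seed = 4)
  s <- c2r(f, hidden = 16, seed = 5)
  expect_equal(dim(s), c(16, 30))
  # identity-like projection reproduces the flattened input when H = D*C
  f2 <- rand3(2, 3, 6, seed = 6)
  s2 <- c2r(f2, hidden = 6, seed = 7,
            params = list("c2r.proj.w" = array(diag(6), c(6, 6, 1)),
                          "c2r.proj.b" = rep(0, 6)))
  expect_close(s2, array(f2, c(6, 6)), 1e-12)
})

test_that("R2C inverts C2R when the projection is the pseudo-inverse", {
  set.seed(8)
  dd <- 2L; cc <- 3L; tt <- 5L; h <- 8L # H >= D*C
  f <- rand3(dd, cc, tt, seed = 9)
  W <- matrix(rnorm(h * dd * cc), h, dd * cc) # c2r map: DC -> H
  s <- c2r(f, hidden = h, seed = 1,
           params = list("c2r.proj.w" = array(W, c(h, dd * cc, 1)),
                         "c2r.proj.b" = rep(0, h)))
  pinv <- solve(t(W) %*% W) %*% t(W) # (DC x H), pinv %*% W = I
  back <- r2c(s, target_depth = dd, target_channels = cc, seed = 1,
              params = list("r2c.proj.w" = array(pinv, c(dd * cc, h, 1)),
                            "r2c.proj.b" = rep(0, dd * cc)))
  expect_close(back, f, 1e-10)
  expect_equal(dim(back), dim(f))
  # zero input with bias-free projection maps to zero
  z <- r2c(matrix(0, h, tt), target_depth = dd, target_channels = cc, seed = 1,
           params = list("r2c.proj.b" = rep(0, dd * cc)))
  expect_close(z, array(0, c(dd, cc, tt)), 1e-12)
})

test_that("fusion produces probabilities and concatenates along depth", {
  cfg <- hafusenet_config("desk", pool = 4L)
  dis_f <- rand3(24, 1, 8, seed = 10)
  ls_s <- matrix(rnorm(40 * 8), 40, 8)
  pr <- fuse_and_classify(dis_f, ls_s, cfg, seed = 11)
  expect_close(rowSums(pr), 1, 1e-12)
  expect_true(all(pr >= 0))
  p <- attr(pr, "params")
  # fused depth = DIS depth + R2C target depth
  expect_equal(nrow(p[["fuse.dw.w"]]), 24L + cfg$r2c_depth)
})

test_that("zeroing the LS projection makes fusion a DIS-only head", {
  cfg <- hafusenet_config("desk", pool = 4L)
  dis_f <- rand3(24, 1, 8, seed = 12)
  ls_a <- matrix(rnorm(40 * 8), 40, 8)
  ls_b <- matrix(rnorm(40 * 8, mean = 3), 40, 8)
  p1 <- fuse_and_classify(dis_f, ls_a, cfg, seed = 13)
  zp <- attr(p1, "params")
  zp[["fuse.r2c.proj.w"]] <- zp[["fuse.r2c.proj.w"]] * 0
  zp[["fuse.r2c.proj.b"]] <- zp[["fuse.r2c.proj.b"]] * 0
  pa <- fuse_and_classify(dis_f, ls_a, cfg, params = zp)
  pb <- fuse_and_classify(dis_f, ls_b, cfg, params = zp)
  expect_close(pa, pb, 1e-12) # recurrent branch has no influence
  expect_gt(max(abs(array(p1, dim(pa)) - pa)), 1e-8) # but normally it does
})

test_that("the full network is deterministic and ablation switches matter", {
  ep <- generate_epochset(synth_config(n_trials_per_class = 1, seed = 5), "S01")
  cfg_full <- tiny_config()
  pr1 <- hafusenet_forward(ep, cfg_full, seed = 3)
  pr2 <- hafusenet_forward(ep, cfg_full, seed = 3)
  expect_identical(as.vector(pr1), as.vector(pr2))
  expect_equal(dim(pr1), c(4L, 4L))
  cfg_noscot <- tiny_config(use_scot = FALSE)
  pr3 <- hafusenet_forward(ep, cfg_noscot, seed = 3)
  expect_gt(max(abs(pr1 - pr3)), 1e-10)
})

test_that("gradients flow into both branches of the fused model", {
  ep <- generate_epochset(synth_config(n_trials_per_class = 1, seed = 6), "S01")
  cfg <- tiny_config()
  ps <- hafusenet:::param_store()
  set.seed(2)
  fw <- hafusenet:::forward_loss(ps, hafusenet:::epochs_to_tensor(ep$data),
                                 ep$labels, cfg, list(training = FALSE))
  hafusenet:::ad_backward(fw$loss)
  norms <- vapply(hafusenet:::ps_grads(ps), function(g) sqrt(sum(g^2)),
                  numeric(1))
  dis_norm <- sum(norms[startsWith(names(norms), "dis.")])
  ls_norm <- sum(norms[startsWith(names(norms), "ls.")])
  fuse_norm <- sum(norms[startsWith(names(norms), "fuse.")])
  expect_gt(dis_norm, 0)
  expect_gt(ls_norm, 0)
  expect_gt(fuse_norm, 0)
})
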