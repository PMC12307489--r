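# DIS-Net backbone: shape contracts, closed-form parameter counts,
# temporal-resolution preservation and the ablation family.

test_that("inverted bottleneck expands, transforms and projects back", {
  x <- rand3(8, 5, 20, seed = 1)
  y <- inverted_bottleneck(x, expansion = 4, kernel = 5, seed = 2)
  expect_equal(dim(y), c(8, 5, 20))
  p <- attr(y, "params")
  expect_equal(dim(p[["bneck.expand.w"]])[1], 32L) # intermediate depth 8*4
  # closed-form parameter count: expand 1x1 + depthwise k + project 1x1
  d <- 8; e <- 4; k <- 5; de <- d * e
  expect_equal(count_parameters(y),
               (de * d + de) + (de * k + de) + (d * de + d))
})

test_that("multi-scale dense block concatenates branches with the input", {
  x <- rand3(8, 5, 30, seed = 3)
  y <- multiscale_dense_block(x, branch_kernels = c(3, 5, 7, 9),
                              branch_depth = 8, seed = 4)
  expect_equal(dim(y), c(8 + 4 * 8, 5, 30)) # 4 branches x 8 + skip 8 = 40
  expect_close(y[1:8, , ], x, 1e-12) # dense skip passes the input through
  yn <- multiscale_dense_block(x, branch_kernels = c(3, 5, 7, 9),
                               branch_depth = 8, dense = FALSE, seed = 4)
  expect_equal(dim(yn), c(32, 5, 30))
  # bias-free configuration maps zero input to zero output
  z <- multiscale_dense_block(array(0, c(8, 5, 30)), c(3, 5), 4, seed = 4)
  p0 <- attr(z, "params")
  p0 <- lapply(p0, function(v) if (length(dim(v)) < 2) v * 0 else v)
  z2 <- multiscale_dense_block(array(0, c(8, 5, 30)), c(3, 5), 4, params = p0)
  expect_close(z2, array(0, dim(z2)), 1e-12)
})

test_that("axial spatial convolution collapses channels separably", {
  x <- rand3(40, 22, 50, seed = 5)
  y <- spatial_depthwise_conv(x, d_out = 16, seed = 6)
  expect_equal(dim(y), c(16, 1, 50))
  # separable parameters < a full non-separable channel-collapsing convolution
  din <- 40; c <- 22; dout <- 16
  sep <- din * c + din + din * dout + dout # depthwise + bias + pointwise + bias
  full <- dout * din * c + dout
  expect_equal(count_parameters(y), sep)
  expect_lt(sep, full)
  # degenerate single-channel input: pointwise mixing only
  x1 <- rand3(4, 1, 10, seed = 7)
  y1 <- spatial_depthwise_conv(x1, d_out = 3, seed = 8)
  expect_equal(dim(y1), c(3, 1, 10))
})

test_that("disnet_forward produces 4 logits and preserves T until pooling", {
  ep <- generate_epochset(synth_config(n_trials_per_class = 2, seed = 3), "S01")
  cfg <- hafusenet_config("desk")
  out <- disnet_forward(ep, cfg, seed = 5)
  expect_equal(ncol(out$logits), 4L)
  expect_equal(nrow(out$logits), 8L)
  # pre-pool features keep the downsampled temporal length
  expect_equal(dim(out$features)[4], 750L %/% cfg$downsample)
  probs <- exp(out$logits) / rowSums(exp(out$logits))
  expect_close(rowSums(probs), rep(1, 8), 1e-12)
  # evaluation-mode determinism
  out2 <- disnet_forward(ep, cfg, seed = 5)
  expect_identical(out$logits, out2$logits)
})

test_that("all six ablation variants are constructible and distinct", {
  variants <- c("inception", "base_inception", "bi_dense", "di_svse",
                "dis_lstm", "hafusenet")
  ep <- generate_epochset(synth_config(n_trials_per_class = 1, seed = 4), "S01")
  counts <- sapply(variants, function(v) {
    cfg <- hafusenet_variant(v, scale = "desk")
    m <- build_hafusenet(dim(ep$data)[2:3], cfg, seed = 1)
    p <- predict(m, ep)
    expect_equal(dim(p), c(4L, 4L))
    m$n_params
  })
  # the family is ordered by construction: each addition brings parameters
  expect_equal(length(unique(counts)), 6L)
  expect_lt(counts[["bi_dense"]], counts[["di_svse"]])
  expect_lt(counts[["di_svse"]], counts[["dis_lstm"]])
  expect_lt(counts[["dis_lstm"]], counts[["hafusenet"]])
  # plain inception variant uses 3 blocks, dense variants 2
  cfg_i <- hafusenet_variant("inception")
  expect_false(cfg_i$use_dense || cfg_i$use_bottleneck || cfg_i$use_svse)
})

test_that("receptive field grows with every added block", {
  # maximum temporal receptive field: stem + per-block largest kernel
  cfg <- hafusenet_config("desk")
  rf <- function(n_blocks) {
    r <- cfg$stem_kernel
    r <- r + (cfg$bottleneck_kernel - 1)
    r + n_blocks * (max(cfg$branch_kernels) - 1)
  }
  expect_true(all(diff(sapply(1:4, rf)) > 0))
})
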