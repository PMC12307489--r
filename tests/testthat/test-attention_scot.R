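# SCoT two-stage attention: Non-local stage invariants, CoT degeneracies,
# composition oracle, and the computational-cost motivation.

test_that("Non-local similarity is row-stochastic for arbitrary inputs", {
  for (seed in 1:3) {
    x <- rand3(4, 6, 10, seed = seed)
    y <- nonlocal_spatial(x, seed = seed + 10)
    s <- attr(y, "similarity")
    expect_equal(dim(s), c(6, 6))
    expect_close(rowSums(array(s, c(6, 6))), rep(1, 6), 1e-10)
    expect_equal(dim(y), dim(x))
  }
})

test_that("Non-local is equivariant under channel permutation", {
  x <- rand3(4, 6, 10, seed = 2)
  y <- nonlocal_spatial(x, seed = 3)
  perm <- c(3, 1, 6, 2, 5, 4)
  yp <- nonlocal_spatial(x[, perm, ], seed = 3, params = attr(y, "params"))
  expect_close(yp, y[, perm, ], 1e-10)
})

test_that("single-token Non-local reduces to residual plus projected value", {
  x <- rand3(4, 1, 8, seed = 6)
  y <- nonlocal_spatial(x, seed = 7)
  p <- attr(y, "params")
  tok <- apply(x, c(1, 2), mean) # depth vector of the only token
  d2 <- 2L
  wg <- array(p[["nl.g.w"]], c(d2, 4))
  wo <- array(p[["nl.out.w"]], c(4, d2))
  proj <- wo %*% (wg %*% tok) # softmax weight over one token is 1
  manual <- x + array(rep(proj, times = 8), c(4, 1, 8))
  expect_close(y, manual, 1e-10)
})

test_that("CoT with zeroed attention convolutions degenerates to the static key", {
  x <- rand3(4, 6, 10, seed = 8)
  y <- cot_temporal(x, kernel = 3, seed = 9,
                    params = list("cot.a2.w" = 0, "cot.a2.b" = 0))
  p <- attr(y, "params")
  key_w <- array(p[["cot.key.w"]], c(4, 3))
  key_b <- as.vector(p[["cot.key.b"]])
  ref <- ref_dwconv(array(x, c(1, dim(x))), key_w, key_b)[1, , , ]
  expect_close(y, ref, 1e-10)
  expect_equal(dim(y), dim(x))
})

test_that("the attention map comes from exactly two chained 1x1 stages", {
  x <- rand3(4, 6, 10, seed = 8)
  y <- cot_temporal(x, seed = 9)
  p <- attr(y, "params")
  a_params <- grep("^cot\\.a[0-9]+\\.w$", names(p), value = TRUE)
  expect_equal(sort(a_params), c("cot.a1.w", "cot.a2.w"))
  expect_equal(dim(p[["cot.a1.w"]])[3], 1L) # 1x1
  expect_equal(dim(p[["cot.a2.w"]])[3], 1L)
  expect_equal(dim(p[["cot.a1.w"]])[2], 8L) # consumes depth-concat of K and Q
})

test_that("scot_apply equals manual chaining and stage order matters", {
  x <- rand3(4, 6, 10, seed = 14)
  out <- scot_apply(x, seed = 15)
  p <- attr(out, "params")
  strip <- function(prefix) {
    sel <- names(p)[startsWith(names(p), paste0("scot.", prefix, "."))]
    stats::setNames(p[sel], sub("^scot\\.", "", sel))
  }
  stage1 <- nonlocal_spatial(x, params = strip("nl"))
  stage2 <- cot_temporal(array(stage1, dim(x)), params = strip("cot"))
  expect_close(out, stage2, 1e-10)
  expect_equal(dim(out), dim(x))
  # reversed order gives a different map on the same weights
  rev1 <- cot_temporal(x, params = strip("cot"))
  rev2 <- nonlocal_spatial(array(rev1, dim(x)), params = strip("nl"))
  expect_gt(max(abs(rev2 - out)), 1e-4)
})

test_that("gradients reach every parameter of both stages", {
  set.seed(31)
  x <- array(rnorm(2 * 4 * 6 * 10), c(2, 4, 6, 10))
  ps <- hafusenet:::param_store()
  set.seed(32)
  hafusenet:::ps_begin(ps)
  out <- hafusenet:::nn_scot(ps, "scot", hafusenet:::ad_leaf(x), list())
  readout <- hafusenet:::ad_matmul(
    hafusenet:::ad_reshape(out, c(1L, length(out$value))),
    hafusenet:::ad_leaf(matrix(rnorm(length(out$value)), ncol = 1)))
  hafusenet:::ad_backward(readout)
  grads <- hafusenet:::ps_grads(ps)
  norms <- vapply(grads, function(g) sqrt(sum(g^2)), numeric(1))
  expect_true(all(norms > 0))
  expect_true(any(startsWith(names(norms), "scot.nl.")))
  expect_true(any(startsWith(names(norms), "scot.cot.")))
})

test_that("two-stage attention costs far less than joint attention", {
  for (t in c(100, 250, 750)) {
    m <- attention_macs(d = 8, c = 22, t = t)
    expect_lt(m$scot, m$joint)
  }
})

test_that("time-resolved token mode preserves shape and differs from pooled", {
  x <- rand3(4, 6, 10, seed = 40)
  yp <- nonlocal_spatial(x, seed = 41)
  yt <- nonlocal_spatial(x, token_mode = "time", seed = 41,
                         params = attr(yp, "params"))
  expect_equal(dim(yt), dim(x))
  expect_gt(max(abs(yt - yp)), 1e-6)
})
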