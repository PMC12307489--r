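# The differentiation engine is the foundation of every fitted model, so each
# operator's backward pass is checked against central finite differences.

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# weighted-sum readout makes the scalar objective sensitive to every output
wsum <- function(node, w) {
  flat <- hafusenet:::ad_reshape(node, c(1L, length(node$value)))
  hafusenet:::ad_matmul(flat, hafusenet:::ad_leaf(matrix(w, ncol = 1)))
}

grad_check <- function(fn, x, tol = 1e-5) {
  leaf <- hafusenet:::ad_leaf(x, requires = TRUE)
  hafusenet:::ad_backward(fn(leaf))
  ag <- leaf$grad
  ng <- num_grad(function(xx)
    as.numeric(fn(hafusenet:::ad_leaf(xx, requires = TRUE))$value), x)
  max(abs(ag - ng)) / max(1, max(abs(ng)))
}

test_that("compiled layer gradients match finite differences", {
  set.seed(42)
  x <- rand4(2, 3, 4, 7, seed = 42)
  w <- array(rnorm(2 * 3 * 3), c(2, 3, 3)); b <- rnorm(2)
  rw <- rnorm(2 * 2 * 4 * 7)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_conv_t(n, hafusenet:::ad_leaf(w),
                               hafusenet:::ad_leaf(b)), rw), x), 1e-5)
  # weight gradient
  leafw <- hafusenet:::ad_leaf(w, requires = TRUE)
  out <- wsum(hafusenet:::ad_conv_t(hafusenet:::ad_leaf(x), leafw,
                                    hafusenet:::ad_leaf(b)), rw)
  hafusenet:::ad_backward(out)
  ngw <- num_grad(function(ww) {
    n2 <- wsum(hafusenet:::ad_conv_t(hafusenet:::ad_leaf(x),
                                     hafusenet:::ad_leaf(ww),
                                     hafusenet:::ad_leaf(b)), rw)
    as.numeric(n2$value)
  }, w)
  expect_lt(max(abs(leafw$grad - ngw)), 1e-5)

  wd <- matrix(rnorm(3 * 3), 3, 3)
  rwx <- rnorm(length(x))
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_dwconv_t(n, hafusenet:::ad_leaf(wd)), rwx), x), 1e-5)

  ws <- matrix(rnorm(3 * 4), 3, 4)
  rws <- rnorm(2 * 3 * 7)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_spconv(n, hafusenet:::ad_leaf(ws), NULL), rws), x), 1e-5)
})

test_that("LSTM backward matches finite differences for all weight groups", {
  set.seed(7)
  B <- 2; Cin <- 3; T <- 5; H <- 3
  xl <- array(rnorm(B * Cin * T), c(B, Cin, T))
  wx <- matrix(rnorm(Cin * 4 * H, sd = 0.5), Cin, 4 * H)
  wh <- matrix(rnorm(H * 4 * H, sd = 0.5), H, 4 * H)
  bl <- rnorm(4 * H, sd = 0.2)
  rwl <- rnorm(B * H * T)
  run <- function(xv, wxv, whv, bv)
    wsum(hafusenet:::ad_lstm(hafusenet:::ad_leaf(xv, requires = TRUE),
                             hafusenet:::ad_leaf(wxv, requires = TRUE),
                             hafusenet:::ad_leaf(whv, requires = TRUE),
                             hafusenet:::ad_leaf(bv, requires = TRUE)), rwl)
  for (target in c("x", "wx", "wh", "b")) {
    args <- list(x = xl, wx = wx, wh = wh, b = bl)
    leaf <- hafusenet:::ad_leaf(args[[target]], requires = TRUE)
    nodes <- lapply(names(args), function(nm)
      if (nm == target) leaf else hafusenet:::ad_leaf(args[[nm]]))
    names(nodes) <- names(args)
    hafusenet:::ad_backward(
      wsum(hafusenet:::ad_lstm(nodes$x, nodes$wx, nodes$wh, nodes$b), rwl))
    ng <- num_grad(function(v) {
      args2 <- args; args2[[target]] <- v
      as.numeric(wsum(hafusenet:::ad_lstm(
        hafusenet:::ad_leaf(args2$x), hafusenet:::ad_leaf(args2$wx),
        hafusenet:::ad_leaf(args2$wh), hafusenet:::ad_leaf(args2$b)),
        rwl)$value)
    }, args[[target]])
    expect_lt(max(abs(leaf$grad - ng)), 1e-5)
  }
})

test_that("reduction, softmax, batch-norm and loss gradients are correct", {
  x <- rand4(2, 3, 4, 6, seed = 9)
  rw <- rnorm(length(x))
  rwm <- rnorm(2 * 1 * 4 * 6)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_mean_axis(n, 2L), rwm), x), 1e-5)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_var_axis(n, 2L), rwm), x), 1e-5)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_softmax_axes(n, c(3L, 4L)), rw), x), 1e-5)
  rwg <- rnorm(6)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_global_max_ct(n), rwg), x), 1e-5)
  rp <- rnorm(2 * 3 * 4 * 2)
  expect_lt(grad_check(function(n)
    wsum(hafusenet:::ad_avgpool_t(n, 3L), rp), x), 1e-5)
  expect_lt(grad_check(function(n) wsum(hafusenet:::ad_gelu(n), rw), x), 1e-5)

  gam <- rnorm(3) + 1; bet <- rnorm(3)
  expect_lt(grad_check(function(n) {
    run <- local({e <- new.env(); e$mean <- rep(0, 3); e$var <- rep(1, 3); e})
    wsum(hafusenet:::ad_batchnorm(n, hafusenet:::ad_leaf(gam),
                                  hafusenet:::ad_leaf(bet), run, TRUE), rw)
  }, x), 1e-4)

  lg <- matrix(rnorm(8), 2, 4)
  lb <- c(2L, 4L)
  expect_lt(grad_check(function(n) hafusenet:::ad_softmax_xent(n, lb), lg), 1e-6)
})

test_that("broadcast kernels agree with base R semantics", {
  a <- rand4(2, 3, 4, 5, seed = 3)
  b <- rand4(1, 1, 4, 5, seed = 4)
  ref <- a; refm <- a; refe <- a
  for (i in 1:2) for (j in 1:3) {
    ref[i, j, , ] <- a[i, j, , ] + b[1, 1, , ]
    refm[i, j, , ] <- a[i, j, , ] * b[1, 1, , ]
    refe[i, j, , ] <- b[1, 1, , ]
  }
  expect_close(hafusenet:::cpp_bin_bcast(a, b, 0L, dim(a)), ref)
  expect_close(hafusenet:::cpp_bin_bcast(a, b, 1L, dim(a)), refm)
  expect_close(hafusenet:::cpp_sum_to(a, c(1L, 3L, 1L, 1L)),
               array(apply(a, 2, sum), c(1, 3, 1, 1)))
  expect_close(hafusenet:::cpp_expand(b, dim(a)), refe)
})
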