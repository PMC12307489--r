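# svSE hybrid attention: every branch against a hand-computed oracle, plus
# the normalization / rank-1 invariants.

softmax_v <- function(v) { e <- exp(v - max(v)); e / sum(e) }

test_that("cSE weights are a depth Softmax with max-pool squeeze", {
  x <- rand3(8, 22, 50, seed = 1)
  a <- cse_weights(x, reduction = 2, seed = 4)
  expect_equal(dim(a), c(8, 1, 1))
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_true(all(a >= 0))
  # constant-across-depth input with a depth-symmetric (identity) excitation:
  # equal logits -> uniform weights 1/D
  xc <- aperm(array(rand3(1, 4, 6, seed = 2)[1, , ], c(4, 6, 5)), c(3, 1, 2))
  id5 <- diag(5)
  ac <- cse_weights(xc, reduction = 1, seed = 4,
                    params = list("cse.fc1.w" = id5, "cse.fc1.b" = rep(0, 5),
                                  "cse.fc2.w" = id5, "cse.fc2.b" = rep(0, 5)))
  expect_close(as.vector(ac), rep(1 / 5, 5), 1e-12)
  # identity excitation preserves the ranking of per-depth maxima
  x3 <- rand3(3, 2, 2, seed = 9)
  id3 <- diag(3)
  a3 <- cse_weights(x3, reduction = 1, seed = 4,
                    params = list("cse.fc1.w" = id3, "cse.fc1.b" = rep(0, 3),
                                  "cse.fc2.w" = id3, "cse.fc2.b" = rep(0, 3)))
  zmax <- apply(x3, 1, max)
  expect_equal(order(as.vector(a3)), order(zmax))
  # r > D falls back to r = 1 with a warning (once per forward pass)
  w <- testthat::capture_warnings(cse_weights(rand3(2, 3, 4), reduction = 8))
  expect_true(all(grepl("falling back", w)) && length(w) >= 1)
})

test_that("variance branch equals the brute-force depth statistics", {
  x <- rand3(4, 3, 5, seed = 12)
  # 1x1 fusion fixed to select the variance plane, no bias
  av <- variance_weights(x, seed = 3,
                         params = list("var.fuse.w" = array(c(0, 1), c(1, 2, 1)),
                                       "var.fuse.b" = 0))
  pre <- attr(av, "pre")
  ref_var <- apply(x, c(2, 3), function(v) mean((v - mean(v))^2))
  expect_close(array(pre, c(3, 5)), ref_var, 1e-10)
  expect_equal(dim(av), c(1, 3, 5))
  expect_equal(sum(av), 1, tolerance = 1e-12)
  # depth-constant input has zero variance everywhere
  xc <- array(1, c(4, 3, 5)) * rep(1, 4)
  avc <- variance_weights(xc, seed = 3,
                          params = list("var.fuse.w" = array(c(0, 1), c(1, 2, 1)),
                                        "var.fuse.b" = 0))
  expect_close(attr(avc, "pre"), array(0, c(1, 3, 5)), 1e-12)
})

test_that("axial weights are the outer product of normalized factors", {
  x <- rand3(5, 3, 4, seed = 7)
  a <- axial_weights(x, seed = 6)
  expect_equal(dim(a), c(1, 3, 4))
  s_n <- attr(a, "s_n"); t_n <- attr(a, "t_n")
  # brute-force outer product oracle
  ref <- outer(as.vector(s_n), as.vector(t_n))
  expect_close(array(a, c(3, 4)), ref, 1e-12)
  # equivalently from the raw factors
  ref2 <- outer(softmax_v(as.vector(attr(a, "x_s"))),
                softmax_v(as.vector(attr(a, "x_t"))))
  expect_close(array(a, c(3, 4)), ref2, 1e-12)
  # rank 1 and sums to 1 over the C x T positions
  sv <- svd(array(a, c(3, 4)))$d
  expect_lt(sv[2], 1e-12)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  # unit left factor: every row proportional to the time factor
  m <- array(a, c(3, 4))
  expect_close(m[1, ] / sum(m[1, ]), as.vector(t_n), 1e-12)
})

test_that("svse_apply equals the hand-chained composition of its branches", {
  x <- rand3(2, 3, 4, seed = 20)
  out <- svse_apply(x, reduction = 2, seed = 5)
  p <- attr(out, "params")
  strip <- function(prefix) {
    sel <- names(p)[startsWith(names(p), paste0("svse.", prefix, "."))]
    stats::setNames(p[sel], sub("^svse\\.", "", sel))
  }
  att_c <- cse_weights(x, reduction = 2, params = strip("cse"))
  att_v <- variance_weights(x, params = strip("var"))
  att_s <- axial_weights(x, params = strip("ax"))
  d <- dim(x)
  att_vs <- array(att_v, d[2:3]) + array(att_s, d[2:3]) # element-wise sum
  manual <- array(0, d)
  for (k in seq_len(d[1]))
    manual[k, , ] <- att_vs * x[k, , ] + as.vector(att_c)[k] * x[k, , ]
  expect_close(out, manual, 1e-10)
  # residual variant adds one input copy on top
  outr <- svse_apply(x, reduction = 2, residual = TRUE, params = p2 <- {
    sel <- names(p); stats::setNames(p[sel], sel)
  })
  expect_close(outr, manual + x, 1e-10)
  # shape preserved; zero input stays zero under multiplicative gating
  expect_equal(dim(out), dim(x))
  z <- svse_apply(array(0, c(2, 3, 4)), seed = 5)
  expect_close(z, array(0, c(2, 3, 4)), 1e-12)
})

test_that("doubling a frozen-weight input scales the output boundedly", {
  x <- rand3(3, 4, 6, seed = 30)
  o1 <- svse_apply(x, seed = 8)
  p <- attr(o1, "params")
  o2 <- svse_apply(2 * x, seed = 8, params = p)
  ratio <- abs(o2[abs(o1) > 1e-6] / o1[abs(o1) > 1e-6])
  # two multiplicative branches with re-normalized weights: factor in [1, 4]
  expect_true(all(ratio >= 1 - 1e-6 & ratio <= 4 + 1e-6))
})
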