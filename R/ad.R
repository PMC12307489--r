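# Tape-based reverse-mode automatic differentiation over dense arrays.
#
# Nodes are environments carrying `value`, an accumulated `grad`, the parent
# nodes, and a vector-Jacobian product closure. The graph is strictly
# feed-forward; `ad_backward()` sorts reachable nodes by creation id and
# pushes gradients parent-ward. Gradient-requiring subgraphs are tracked via
# `requires`, so evaluation-only forwards build no closures.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_is_node <- function(x) inherits(x, "ad_node")

#' @noRd
ad_leaf <- function(value, requires = FALSE) {
  n <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  n$id <- .ad$counter
  n$value <- value
  n$grad <- NULL
  n$parents <- list()
  n$vjp <- NULL
  n$requires <- requires
  class(n) <- "ad_node"
  n
}

ad_val <- function(x) if (ad_is_node(x)) x$value else x

ad_wrap <- function(x) if (ad_is_node(x)) x else ad_leaf(x, requires = FALSE)

# Build an op node. `vjp(g)` must return a list of gradients aligned with
# `parents` (NULL entries allowed for non-differentiable parents).
ad_op <- function(value, parents, vjp) {
  req <- any(vapply(parents, function(p) isTRUE(p$requires), logical(1)))
  n <- ad_leaf(value, requires = req)
  if (req) {
    n$parents <- parents
    n$vjp <- vjp
  }
  n
}

#' @noRd
ad_backward <- function(root, seed_grad = NULL) {
  if (is.null(seed_grad)) seed_grad <- array(1, dim = dim_or1(root$value))
  root$grad <- seed_grad
  # collect reachable differentiable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) if (isTRUE(p$requires)) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, numeric(1))
  for (n in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(n$vjp) || is.null(n$grad)) next
    gs <- n$vjp(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!isTRUE(p$requires) || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    n$grad <- NULL # free as we go
  }
  invisible(root)
}

dim_or1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- broadcasting helpers (compiled kernels over <= 4-d arrays) ---------------

# Expand array `a` to `target` dims; axes may only differ where dim(a) == 1.
bc_expand <- function(a, target) {
  da <- dim_or1(a)
  if (length(da) != length(target)) stop("broadcast rank mismatch")
  if (all(da == target)) return(a)
  if (any(da != target & da != 1L)) stop("incompatible broadcast shapes")
  cpp_expand(a, as.integer(target))
}

# Sum over axis k, keeping it as a singleton.
axis_sum <- function(g, k) {
  d <- dim_or1(g)
  cpp_sum_to(g, as.integer(replace(d, k, 1L)))
}

# Reduce gradient `g` back to shape `da` (inverse of bc_expand).
bc_reduce <- function(g, da) {
  dg <- dim_or1(g)
  if (length(dg) == length(da) && all(dg == da)) return(g)
  out <- cpp_sum_to(g, as.integer(da))
  if (length(da) == 1L) dim(out) <- NULL
  out
}

# ---- elementwise / structural ops -------------------------------------------

ad_add <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  da <- dim_or1(a$value); db <- dim_or1(b$value)
  tg <- as.integer(pmax(da, db))
  val <- cpp_bin_bcast(a$value, b$value, 0L, tg)
  ad_op(val, list(a, b), function(g) list(bc_reduce(g, da), bc_reduce(g, db)))
}

ad_sub <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  da <- dim_or1(a$value); db <- dim_or1(b$value)
  tg <- as.integer(pmax(da, db))
  val <- cpp_bin_bcast(a$value, b$value, 2L, tg)
  ad_op(val, list(a, b), function(g) list(bc_reduce(g, da), -bc_reduce(g, db)))
}

ad_mul <- function(a, b) {
  a <- ad_wrap(a); b <- ad_wrap(b)
  da <- dim_or1(a$value); db <- dim_or1(b$value)
  tg <- as.integer(pmax(da, db))
  val <- cpp_bin_bcast(a$value, b$value, 1L, tg)
  ad_op(val, list(a, b), function(g)
    list(bc_reduce(cpp_bin_bcast(g, b$value, 1L, tg), da),
         bc_reduce(cpp_bin_bcast(g, a$value, 1L, tg), db)))
}

ad_scale <- function(a, s) {
  ad_op(a$value * s, list(a), function(g) list(g * s))
}

ad_reshape <- function(a, dims) {
  od <- dim_or1(a$value)
  v <- a$value
  dim(v) <- dims
  ad_op(v, list(a), function(g) { dim(g) <- od; list(g) })
}

ad_aperm <- function(a, perm) {
  inv <- order(perm)
  ad_op(aperm(a$value, perm), list(a), function(g) list(aperm(g, inv)))
}

ad_concat_depth <- function(nodes) {
  vals <- lapply(nodes, `[[`, "value")
  ds <- vapply(vals, function(v) dim(v)[2], integer(1))
  out <- cpp_concat_depth(vals)
  ad_op(out, nodes, function(g) cpp_split_depth(g, ds))
}

# ---- activations -------------------------------------------------------------

ad_gelu <- function(a) {
  xv <- a$value
  ad_op(cpp_gelu_fw(xv), list(a), function(g) list(cpp_gelu_bw(xv, g)))
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  ad_op(y, list(a), function(g) list(g * y * (1 - y)))
}

ad_tanh <- function(a) {
  y <- tanh(a$value)
  ad_op(y, list(a), function(g) list(g * (1 - y * y)))
}

# Row-wise softmax of a matrix (N x K).
ad_softmax_rows <- function(a) {
  x <- a$value
  m <- x - apply(x, 1L, max)
  e <- exp(m)
  y <- e / rowSums(e)
  ad_op(y, list(a), function(g) list(y * (g - rowSums(g * y))))
}

# Softmax over one axis (or flattened axes) of a 4-d tensor, keeping shape.
ad_softmax_axes <- function(a, axes) {
  d <- dim(a$value)
  rest <- setdiff(seq_along(d), axes)
  perm <- c(rest, axes)
  n <- prod(d[rest]); k <- prod(d[axes])
  ap <- ad_aperm(a, perm)
  am <- ad_reshape(ap, c(n, k))
  sm <- ad_softmax_rows(am)
  back <- ad_reshape(sm, d[perm])
  ad_aperm(back, order(perm))
}

# ---- reductions --------------------------------------------------------------

ad_mean_axis <- function(a, k) {
  d <- dim(a$value)
  v <- axis_sum(a$value, k) / d[k]
  ad_op(v, list(a), function(g) list(bc_expand(g, d) / d[k]))
}

# Population variance over axis k (keepdim).
ad_var_axis <- function(a, k) {
  d <- dim(a$value)
  m <- axis_sum(a$value, k) / d[k]
  cent <- a$value - bc_expand(m, d)
  v <- axis_sum(cent * cent, k) / d[k]
  ad_op(v, list(a), function(g)
    list(cpp_bin_bcast(g, cent, 1L, as.integer(d)) * (2 / d[k])))
}

# Max over axis k (keepdim); ties broken by first index for determinism.
ad_max_axis <- function(a, k) {
  d <- dim(a$value)
  perm <- c(k, setdiff(seq_along(d), k))
  m <- array(aperm(a$value, perm), dim = c(d[k], prod(d[-k])))
  idx <- max.col(t(m), ties.method = "first")
  val <- m[cbind(idx, seq_along(idx))]
  # perm keeps the non-k axes in original order, and inserting a singleton
  # axis does not change column-major layout
  out <- array(val, dim = replace(d, k, 1L))
  ad_op(out, list(a), function(g) {
    gm <- matrix(0, nrow = d[k], ncol = prod(d[-k]))
    gm[cbind(idx, seq_along(idx))] <- as.vector(g)
    gm <- array(gm, dim = d[perm])
    list(aperm(gm, order(perm)))
  })
}

# Global max over channel and time axes: (B, D, C, T) -> (B, D, 1, 1).
ad_global_max_ct <- function(a) {
  d <- dim(a$value)
  m <- array(a$value, dim = c(d[1] * d[2], d[3] * d[4]))
  idx <- max.col(m, ties.method = "first")
  val <- m[cbind(seq_along(idx), idx)]
  out <- array(val, dim = c(d[1], d[2], 1L, 1L))
  ad_op(out, list(a), function(g) {
    gm <- matrix(0, nrow = d[1] * d[2], ncol = d[3] * d[4])
    gm[cbind(seq_along(idx), idx)] <- as.vector(g)
    list(array(gm, dim = d))
  })
}

# Non-overlapping average pooling over time; trailing remainder is cropped.
ad_avgpool_t <- function(a, k) {
  if (k <= 1L) return(a)
  d <- dim(a$value)
  tout <- d[4] %/% k
  v <- a$value
  if (tout * k < d[4]) v <- v[, , , seq_len(tout * k), drop = FALSE]
  dim(v) <- c(d[1] * d[2] * d[3], k, tout)
  pooled <- colSums(aperm(v, c(2, 1, 3)), dims = 1L) / k
  out <- array(pooled, dim = c(d[1], d[2], d[3], tout))
  ad_op(out, list(a), function(g) {
    ge <- array(0, dim = c(d[1] * d[2] * d[3], k, tout))
    gflat <- array(g, dim = c(d[1] * d[2] * d[3], tout))
    for (j in seq_len(k)) ge[, j, ] <- gflat / k
    gx <- array(0, dim = d)
    gx[, , , seq_len(tout * k)] <- array(ge, dim = c(d[1], d[2], d[3], tout * k))
    list(gx)
  })
}

# ---- linear algebra ----------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_op(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

# Batched matrix multiply: (B, n, m) x (B, m, p) -> (B, n, p).
ad_bmm <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  B <- da[1]
  out <- array(0, dim = c(B, da[2], db[3]))
  for (i in seq_len(B))
    out[i, , ] <- array(av[i, , ], da[2:3]) %*% array(bv[i, , ], db[2:3])
  ad_op(out, list(a, b), function(g) {
    ga <- array(0, dim = da); gb <- array(0, dim = db)
    for (i in seq_len(B)) {
      gi <- array(g[i, , ], c(da[2], db[3]))
      ai <- array(av[i, , ], da[2:3]); bi <- array(bv[i, , ], db[2:3])
      ga[i, , ] <- gi %*% t(bi)
      gb[i, , ] <- t(ai) %*% gi
    }
    list(ga, gb)
  })
}

ad_linear <- function(x, w, b = NULL) {
  out <- ad_matmul(x, w)
  if (!is.null(b)) {
    bn <- ad_reshape(b, c(1L, length(b$value)))
    out <- ad_add(out, bn)
  }
  out
}

# ---- compiled layers ---------------------------------------------------------

# Temporal convolution with same padding. x: (B, Din, C, T); w: (Dout, Din, K).
ad_conv_t <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  has_b <- !is.null(b)
  y <- cpp_conv_t_fw(xv, wv, if (has_b) b$value else NULL)
  parents <- if (has_b) list(x, w, b) else list(x, w)
  ad_op(y, parents, function(g) {
    r <- cpp_conv_t_bw(xv, wv, g, has_b)
    if (has_b) list(r$gx, r$gw, r$gb) else list(r$gx, r$gw)
  })
}

# Depthwise temporal convolution. w: (D, K).
ad_dwconv_t <- function(x, w) {
  xv <- x$value; wv <- w$value
  y <- cpp_dwconv_t_fw(xv, wv)
  ad_op(y, list(x, w), function(g) {
    r <- cpp_dwconv_t_bw(xv, wv, g)
    list(r$gx, r$gw)
  })
}

# Axial spatial convolution collapsing the channel axis. w: (D, C).
ad_spconv <- function(x, w, b = NULL) {
  xv <- x$value; wv <- w$value
  has_b <- !is.null(b)
  y <- cpp_spconv_fw(xv, wv, if (has_b) b$value else NULL)
  parents <- if (has_b) list(x, w, b) else list(x, w)
  ad_op(y, parents, function(g) {
    r <- cpp_spconv_bw(xv, wv, g, has_b)
    if (has_b) list(r$gx, r$gw, r$gb) else list(r$gx, r$gw)
  })
}

# Single LSTM layer over (B, Cin, T); returns hidden sequence (B, H, T).
ad_lstm <- function(x, wx, wh, b) {
  xv <- x$value
  fw <- cpp_lstm_fw(xv, wx$value, wh$value, b$value)
  ad_op(fw$y, list(x, wx, wh, b), function(g) {
    r <- cpp_lstm_bw(xv, wx$value, wh$value, fw$gates, fw$c, fw$y, g)
    list(r$gx, r$gwx, r$gwh, as.vector(r$gb))
  })
}

# Inverted dropout; identity when not training or p == 0.
ad_dropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- array(stats::rbinom(length(x$value), 1L, 1 - p) / (1 - p),
                dim = dim_or1(x$value))
  ad_op(x$value * mask, list(x), function(g) list(g * mask))
}

# Batch normalization per depth map over (B, C, T).
# `run` is an environment with $mean / $var updated in training mode.
ad_batchnorm <- function(x, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$value)
  dd <- as.integer(c(1L, d[2], 1L, 1L))
  n <- d[1] * d[3] * d[4]
  sum_d <- function(v) cpp_sum_to(v, dd)
  if (training) {
    mu <- sum_d(x$value) / n
    cent <- cpp_bin_bcast(x$value, mu, 2L, as.integer(d))
    va <- sum_d(cent * cent) / n
    run$mean <- (1 - momentum) * run$mean + momentum * as.vector(mu)
    run$var <- (1 - momentum) * run$var + momentum * as.vector(va) * n / max(1, n - 1)
  } else {
    mu <- array(run$mean, dim = dd)
    va <- array(run$var, dim = dd)
    cent <- cpp_bin_bcast(x$value, mu, 2L, as.integer(d))
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- cpp_bin_bcast(cent, istd, 1L, as.integer(d))
  gv <- array(gamma$value, dim = dd)
  bv <- array(beta$value, dim = dd)
  y <- cpp_bin_bcast(cpp_bin_bcast(xhat, gv, 1L, as.integer(d)), bv, 0L,
                     as.integer(d))
  ad_op(y, list(x, gamma, beta), function(g) {
    gg <- as.vector(sum_d(g * xhat))
    gb <- as.vector(sum_d(g))
    gxh <- cpp_bin_bcast(g, gv, 1L, as.integer(d))
    if (training) {
      sm <- sum_d(gxh) / n
      sx <- sum_d(gxh * xhat) / n
      gx <- cpp_bin_bcast(
        gxh - cpp_bin_bcast(xhat, sx, 1L, as.integer(d)) -
          cpp_expand(sm, as.integer(d)),
        istd, 1L, as.integer(d))
    } else {
      gx <- cpp_bin_bcast(gxh, istd, 1L, as.integer(d))
    }
    list(gx, gg, gb)
  })
}

# Mean categorical cross-entropy with integrated softmax.
# logits: (B, K); labels: integer vector in 1..K.
ad_softmax_xent <- function(logits, labels, eps = 1e-12) {
  x <- logits$value
  m <- x - apply(x, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  B <- nrow(x)
  ix <- cbind(seq_len(B), labels)
  loss <- -mean(log(pmax(p[ix], eps)))
  ad_op(loss, list(logits), function(g) {
    gp <- p
    gp[ix] <- gp[ix] - 1
    list(gp * (as.numeric(g) / B))
  })
}
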