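# svSE: hybrid variance-informed spatial + channel squeeze-and-excitation.
#
# Three weighting branches over a feature tensor X in R^{D x C x T}
# (D feature maps, C electrodes, T samples):
#   att_c (D x 1 x 1): global-max squeeze over (C, T), reduce-expand
#           excitation, Softmax over depth;
#   att_v (1 x C x T): depth-mean and depth-variance stacked, fused by a
#           1x1 convolution, Softmax over the C*T positions;
#   att_s (1 x C x T): axial attention -- a channel factor (C x 1) and a time
#           factor (1 x T), each Softmax-normalized, recombined by Kronecker
#           product, hence rank-1 over C x T and summing to 1.
# The fused output is X_svSE = (att_v + att_s) (x) X + att_c (x) X.

# internal tape-level branches ---------------------------------------------------

nn_cse <- function(ps, pre, x, reduction = 2L) {
  d <- dim(x$value)[2]
  r <- reduction
  if (d < r) {
    warning("cSE reduction ratio exceeds depth; falling back to r = 1")
    r <- 1L
  }
  dmid <- max(1L, d %/% r)
  z <- ad_global_max_ct(x)                       # (B, D, 1, 1)
  z <- ad_reshape(z, c(dim(x$value)[1], d))
  z <- nn_linear(ps, paste0(pre, ".fc1"), z, dmid)
  z <- ad_gelu(z)
  z <- nn_linear(ps, paste0(pre, ".fc2"), z, d)
  a <- ad_softmax_rows(z)                        # Softmax over depth
  ad_reshape(a, c(dim(x$value)[1], d, 1L, 1L))
}

nn_variance <- function(ps, pre, x, return_pre = FALSE) {
  xm <- ad_mean_axis(x, 2L)                      # (B, 1, C, T)
  xv <- ad_var_axis(x, 2L)                       # population variance
  pool <- ad_concat_depth(list(xm, xv))          # (B, 2, C, T)
  pre_act <- nn_conv1x1(ps, paste0(pre, ".fuse"), pool, 1L)
  att <- ad_softmax_axes(pre_act, c(3L, 4L))
  if (return_pre) list(att = att, pre = pre_act, pool = pool) else att
}

nn_axial <- function(ps, pre, x, return_inter = FALSE) {
  x_sf <- nn_conv1x1(ps, paste0(pre, ".sf"), x, 1L)      # (B, 1, C, T)
  s_avg <- ad_mean_axis(x_sf, 4L)                        # (B, 1, C, 1)
  s_max <- ad_max_axis(x_sf, 4L)
  x_spool <- ad_concat_depth(list(s_avg, s_max))         # (B, 2, C, 1)
  x_s <- nn_conv1x1(ps, paste0(pre, ".sfuse"), x_spool, 1L)  # (B, 1, C, 1)
  x_t <- nn_spconv(ps, paste0(pre, ".time"), x_sf)       # (B, 1, 1, T)
  s_n <- ad_softmax_axes(x_s, 3L)
  t_n <- ad_softmax_axes(x_t, 4L)
  att <- ad_mul(s_n, t_n)                                # Kronecker recombination
  if (return_inter)
    list(att = att, x_sf = x_sf, x_spool = x_spool, x_s = x_s, x_t = x_t,
         s_n = s_n, t_n = t_n)
  else att
}

nn_svse <- function(ps, pre, x, cfg = list()) {
  reduction <- cfg$svse_reduction %||% 2L
  residual <- isTRUE(cfg$svse_residual)
  att_c <- nn_cse(ps, paste0(pre, ".cse"), x, reduction)
  att_v <- nn_variance(ps, paste0(pre, ".var"), x)
  att_s <- nn_axial(ps, paste0(pre, ".ax"), x)
  att_vs <- ad_add(att_v, att_s)
  # (att_vs (x) X) (+) (att_c (x) X) computed distributively as one gated
  # product X (x) (att_vs (+) att_c); identical by bilinearity
  out <- ad_mul(ad_add(att_vs, att_c), x)
  # Softmax-normalized maps sum to 1 over their axis, so the multiplicative
  # paths shrink activations by roughly 1/(C*T) + 1/D per stage; the residual
  # copy keeps the signal scale stable through stacked svSE stages.
  if (residual) out <- ad_add(out, x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exported layer-style surface ---------------------------------------------------

#' Channel excitation weights (cSE branch of svSE)
#'
#' Squeezes each depth map by a global max over electrodes and time,
#' passes the D-vector through a reduce--expand excitation (one hidden layer,
#' GELU), and normalizes with a Softmax over depth, so the returned weights
#' sum to 1.
#'
#' @param x numeric array, `(D, C, T)` or `(B, D, C, T)`.
#' @param reduction integer reduction ratio `r` of the excitation; if `r > D`
#'   it falls back to 1 with a warning.
#' @param params optional named list of parameter overrides (see
#'   `attr(result, "params")` for the realized names and shapes).
#' @param seed integer seed fixing the parameter initialization.
#' @return array `(D, 1, 1)` (or batched) of non-negative weights summing to 1
#'   over depth; realized parameters in `attr(, "params")`.
#' @export
cse_weights <- function(x, reduction = 2L, params = NULL, seed = 1L) {
  module_run(x, function(ps, xn, ctx) nn_cse(ps, "cse", xn, reduction),
             seed = seed, params = params)
}

#' Variance-informed spatio-temporal weights (sSE variance branch of svSE)
#'
#' Stacks the depth-wise mean and (population) variance at every
#' (electrode, time) position, fuses them with a 1x1 convolution and applies
#' a Softmax over the flattened C x T positions.
#'
#' @inheritParams cse_weights
#' @return array `(1, C, T)` (or batched) summing to 1 over positions, with
#'   the pre-Softmax fused map in `attr(, "pre")` and the stacked mean/variance
#'   planes in `attr(, "pool")`.
#' @export
variance_weights <- function(x, params = NULL, seed = 1L) {
  out <- module_run(x, function(ps, xn, ctx) nn_variance(ps, "var", xn, TRUE),
                    seed = seed, params = params)
  att <- out$att
  attr(att, "pre") <- out$pre
  attr(att, "pool") <- out$pool
  attr(att, "params") <- attr(out, "params")
  att
}

#' Axial (channel x time) rank-1 attention weights (svSE spatial branch)
#'
#' Depth-compresses the input with a 1x1 convolution, derives a channel factor
#' from time-axis average and max pooling fused by a 1x1 convolution, and a
#' time factor from a C x 1 convolution spanning the whole channel axis. Each
#' factor is Softmax-normalized on its own axis and the two are recombined by
#' Kronecker (outer) product, so the C x T weight map has rank 1 and sums to 1.
#'
#' @inheritParams cse_weights
#' @return array `(1, C, T)` (or batched); intermediates `x_sf`, `x_spool`,
#'   `x_s`, `x_t` (pre-Softmax) and the normalized factors `s_n`, `t_n` are
#'   attached as attributes.
#' @export
axial_weights <- function(x, params = NULL, seed = 1L) {
  out <- module_run(x, function(ps, xn, ctx) nn_axial(ps, "ax", xn, TRUE),
                    seed = seed, params = params)
  att <- out$att
  for (nm in c("x_sf", "x_spool", "x_s", "x_t", "s_n", "t_n"))
    attr(att, nm) <- out[[nm]]
  attr(att, "params") <- attr(out, "params")
  att
}

#' Apply the svSE hybrid attention module
#'
#' Computes the three svSE weight branches and fuses them:
#' `att_vs = att_v + att_s`, output `= att_vs (x) X + att_c (x) X`
#' (element-wise products broadcast over singleton axes), preserving the
#' input shape. An optional residual copy of X can be added.
#'
#' @inheritParams cse_weights
#' @param residual logical; add a residual copy of the input (default FALSE).
#' @return array of the same shape as `x`; realized parameters in
#'   `attr(, "params")`.
#' @export
svse_apply <- function(x, reduction = 2L, residual = FALSE, params = NULL,
                       seed = 1L) {
  cfg <- list(svse_reduction = reduction, svse_residual = residual)
  module_run(x, function(ps, xn, ctx) nn_svse(ps, "svse", xn, cfg),
             seed = seed, params = params)
}
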