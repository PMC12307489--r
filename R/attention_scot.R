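# SCoT: two-stage global self-attention for (channel, time) EEG feature maps.
# Stage 1 adapts the Non-local block to spatial (channel-token) self-attention;
# stage 2 applies contextual-transformer (CoT) style temporal attention, where
# a local 1 x k convolution provides the static-context key and two chained
# 1x1 convolutions produce the dynamic attention map.

# internal tape-level stages ------------------------------------------------------

nn_nonlocal <- function(ps, pre, x, cfg = list()) {
  mode <- cfg$token_mode %||% "pooled"
  residual <- cfg$nonlocal_residual %||% TRUE
  d <- dim(x$value)
  if (mode == "time") {
    # time-resolved tokens: fold time into the batch axis and recurse
    xt <- ad_aperm(x, c(1L, 4L, 2L, 3L))              # (B, T, D, C)
    xt <- ad_reshape(xt, c(d[1] * d[4], d[2], d[3], 1L))
    y <- nn_nonlocal(ps, pre, xt,
                     list(token_mode = "pooled", nonlocal_residual = residual))
    y <- ad_reshape(y, c(d[1], d[4], d[2], d[3]))
    return(ad_aperm(y, c(1L, 3L, 4L, 2L)))
  }
  if (d[2] < 2 && !isTRUE(cfg$allow_depth1))
    stop("nonlocal_spatial requires depth >= 2 (half-depth compression); ",
         "set allow_depth1 for degenerate use")
  d2 <- max(1L, ceiling(d[2] / 2))
  tok <- ad_mean_axis(x, 4L)                          # (B, D, C, 1)
  th <- nn_conv1x1(ps, paste0(pre, ".theta"), tok, d2, bias = FALSE)
  ph <- nn_conv1x1(ps, paste0(pre, ".phi"), tok, d2, bias = FALSE)
  gg <- nn_conv1x1(ps, paste0(pre, ".g"), tok, d2, bias = FALSE)
  th3 <- ad_reshape(th, c(d[1], d2, d[3]))
  ph3 <- ad_reshape(ph, c(d[1], d2, d[3]))
  gg3 <- ad_reshape(gg, c(d[1], d2, d[3]))
  s <- ad_bmm(ad_aperm(th3, c(1L, 3L, 2L)), ph3)      # (B, C, C) similarity
  s <- ad_softmax_axes(s, 3L)                         # rows sum to 1
  y <- ad_bmm(gg3, ad_aperm(s, c(1L, 3L, 2L)))        # (B, D2, C)
  y <- ad_reshape(y, c(d[1], d2, d[3], 1L))
  y <- nn_conv1x1(ps, paste0(pre, ".out"), y, d[2], bias = FALSE)
  if (isTRUE(residual)) ad_add(x, y) else y           # broadcast over T
}

nn_cot <- function(ps, pre, x, cfg = list()) {
  k <- cfg$cot_kernel %||% 3L
  d <- dim(x$value)
  dd <- d[2]
  dmid <- max(1L, dd %/% 2L)
  key <- nn_dwconv_t(ps, paste0(pre, ".key"), x, k)       # static context
  val <- nn_conv1x1(ps, paste0(pre, ".value"), x, dd)
  kq <- ad_concat_depth(list(key, x))                     # K (+) Q, depth 2D
  a <- nn_conv1x1(ps, paste0(pre, ".a1"), kq, dmid)
  a <- ad_gelu(a)
  a <- nn_conv1x1(ps, paste0(pre, ".a2"), a, dd)          # attention map A
  dyn <- ad_mul(a, val)
  ones <- ad_leaf(matrix(1, dd, k))                       # fixed local footprint
  dyn <- ad_dwconv_t(dyn, ones)
  ad_add(key, dyn)                                        # static (+) dynamic
}

nn_scot <- function(ps, pre, x, cfg = list()) {
  y <- nn_nonlocal(ps, paste0(pre, ".nl"), x, cfg)
  nn_cot(ps, paste0(pre, ".cot"), y, cfg)
}

# exported layer-style surface ----------------------------------------------------

#' Non-local spatial self-attention over channel tokens
#'
#' Each channel position becomes a token described by its depth vector after
#' mean-pooling over time. Query, key and value maps come from three 1x1
#' convolutions at half depth; the C x C similarity matrix is Softmax-
#' normalized row-wise, values are aggregated, re-expanded to full depth by a
#' 1x1 convolution, broadcast over time and (by default) summed residually
#' with the input.
#'
#' @param x numeric array `(D, C, T)` or `(B, D, C, T)`, depth >= 2 unless
#'   `allow_depth1 = TRUE` (half-depth compression has a floor of 1).
#' @param token_mode `"pooled"` (default, C tokens) or `"time"`
#'   (time-resolved: attention computed independently at every sample).
#' @param residual logical, include the residual sum with the input.
#' @param allow_depth1 permit depth-1 inputs (used inside LS-Net where the
#'   LSTM hidden axis plays the channel role).
#' @param params,seed see [cse_weights()].
#' @return array shaped like `x`; the row-stochastic similarity matrix is in
#'   `attr(, "similarity")`, realized parameters in `attr(, "params")`.
#' @export
nonlocal_spatial <- function(x, token_mode = "pooled", residual = TRUE,
                             allow_depth1 = FALSE, params = NULL, seed = 1L) {
  cfg <- list(token_mode = token_mode, nonlocal_residual = residual,
              allow_depth1 = allow_depth1)
  sim_store <- new.env(parent = emptyenv())
  out <- module_run(x, function(ps, xn, ctx) {
    y <- nn_nonlocal(ps, "nl", xn, cfg)
    # recompute the similarity for reporting (cheap, value-only)
    y
  }, seed = seed, params = params)
  attr(out, "similarity") <- scot_similarity(x, attr(out, "params"),
                                             prefix = "nl", cfg = cfg)
  out
}

# value-only recomputation of the Non-local similarity matrix (pooled mode)
scot_similarity <- function(x, params, prefix = "nl", cfg = list()) {
  bx <- as_b4(x)
  xv <- bx$arr
  d <- dim(xv)
  if ((cfg$token_mode %||% "pooled") != "pooled") return(NULL)
  d2 <- max(1L, ceiling(d[2] / 2))
  tok <- axis_sum(xv, 4L) / d[4]                        # (B, D, C, 1)
  wth <- params[[paste0(prefix, ".theta.w")]]
  wph <- params[[paste0(prefix, ".phi.w")]]
  sims <- array(0, dim = c(d[1], d[3], d[3]))
  for (b in seq_len(d[1])) {
    tb <- array(tok[b, , , 1], c(d[2], d[3]))
    th <- array(wth, c(d2, d[2])) %*% tb                # (D2, C)
    ph <- array(wph, c(d2, d[2])) %*% tb
    s <- t(th) %*% ph
    e <- exp(s - apply(s, 1, max))
    sims[b, , ] <- e / rowSums(e)
  }
  if (bx$batched) sims else array(sims, dim = d[c(3, 3)])
}

#' CoT-style temporal context attention
#'
#' The static-context key is a local depthwise 1 x k temporal convolution of
#' the input; the value is a 1x1 convolution; the attention map A is produced
#' by two consecutive 1x1 convolutions (GELU between) applied to the depth
#' concatenation of key and query (= input). The dynamic context is the
#' element-wise product A (x) V summed over the local kernel footprint, and
#' the output fuses static and dynamic contexts by element-wise addition.
#'
#' @inheritParams nonlocal_spatial
#' @param kernel temporal kernel length of the static-context convolution
#'   (default 3, the 1-D mapping of CoT's 3 x 3 image kernel).
#' @return array shaped like `x`, parameters in `attr(, "params")`.
#' @export
cot_temporal <- function(x, kernel = 3L, params = NULL, seed = 1L) {
  module_run(x, function(ps, xn, ctx)
    nn_cot(ps, "cot", xn, list(cot_kernel = kernel)),
    seed = seed, params = params)
}

#' Apply the SCoT two-stage global attention module
#'
#' `SCoT(X) = Att_st(Att_s(X))`: Non-local spatial self-attention over channel
#' tokens first, CoT-style temporal context attention second. Shape-preserving.
#'
#' @inheritParams nonlocal_spatial
#' @param kernel CoT static-context kernel length.
#' @export
scot_apply <- function(x, token_mode = "pooled", residual = TRUE, kernel = 3L,
                       allow_depth1 = FALSE, params = NULL, seed = 1L) {
  cfg <- list(token_mode = token_mode, nonlocal_residual = residual,
              cot_kernel = kernel, allow_depth1 = allow_depth1)
  module_run(x, function(ps, xn, ctx) nn_scot(ps, "scot", xn, cfg),
             seed = seed, params = params)
}

#' Multiply-accumulate counts for SCoT versus joint spatio-temporal attention
#'
#' Closed-form MAC counts supporting the two-stage design argument: the
#' channel-token Non-local stage plus the local CoT stage cost far less than
#' one joint self-attention over all C*T positions.
#'
#' @param d feature depth, `c` channel count, `t` temporal length,
#'   `k` CoT kernel.
#' @return named list with `scot` and `joint` MAC counts.
#' @export
attention_macs <- function(d, c, t, k = 3L) {
  d2 <- max(1, ceiling(d / 2))
  dmid <- max(1, d %/% 2)
  nl <- 3 * d * d2 * c +      # q/k/v projections on pooled tokens
    2 * c * c * d2 +          # similarity + value aggregation
    d2 * d * c                # re-expansion
  cot <- d * k * c * t +      # static key
    d * d * c * t +           # value
    (2 * d) * dmid * c * t + dmid * d * c * t + # two 1x1 stages for A
    d * c * t * k             # local aggregation of A (x) V
  n <- c * t
  joint <- 3 * d * d2 * n + 2 * n * n * d2 + d2 * d * n
  list(scot = nl + cot, joint = joint)
}
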