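# DIS-Net: the convolutional branch. Stem temporal convolution, inverted
# bottleneck, multi-scale (dense) blocks with svSE, axial depthwise-separable
# spatial convolution, pooled classification head. Every stage preserves the
# temporal length T; only the head pooling reduces it.

nn_bottleneck <- function(ps, pre, x, expansion, kernel) {
  d <- dim(x$value)[2]
  y <- nn_conv1x1(ps, paste0(pre, ".expand"), x, d * expansion)
  y <- ad_gelu(y)
  y <- nn_dwconv_t(ps, paste0(pre, ".dw"), y, kernel)
  nn_conv1x1(ps, paste0(pre, ".project"), y, d)
}

nn_dense_block <- function(ps, pre, x, cfg, ctx) {
  branches <- lapply(seq_along(cfg$branch_kernels), function(i) {
    b <- nn_temporal_conv(ps, sprintf("%s.branch%d", pre, i), x,
                          cfg$branch_depth, cfg$branch_kernels[i], cfg, ctx)
    ad_gelu(b)
  })
  parts <- if (isTRUE(cfg$use_dense)) c(list(x), branches) else branches
  ad_concat_depth(parts)
}

nn_spatial_sep <- function(ps, pre, x, d_out) {
  y <- nn_spconv(ps, paste0(pre, ".dw"), x)         # (B, D, 1, T)
  y <- nn_conv1x1(ps, paste0(pre, ".pw"), y, d_out) # pointwise mixing
  ad_gelu(y)
}

nn_head <- function(ps, pre, x, cfg, ctx) {
  pooled <- ad_avgpool_t(x, cfg$pool)
  d <- dim(pooled$value)
  flat <- ad_reshape(pooled, c(d[1], prod(d[-1])))
  flat <- ad_dropout(flat, cfg$dropout, isTRUE(ctx$training))
  if ((cfg$fc_hidden %||% 0L) > 0L) {
    flat <- ad_gelu(nn_linear(ps, paste0(pre, ".fc0"), flat, cfg$fc_hidden))
  }
  nn_linear(ps, paste0(pre, ".fc"), flat, cfg$n_classes)
}

# full DIS-Net branch; returns the pre-pool feature map and the branch logits
nn_disnet <- function(ps, pre, x, cfg, ctx) {
  y <- nn_temporal_conv(ps, paste0(pre, ".stem"), x, cfg$stem_depth,
                        cfg$stem_kernel, cfg, ctx)
  y <- ad_gelu(y)
  if (isTRUE(cfg$use_bottleneck))
    y <- nn_bottleneck(ps, paste0(pre, ".bneck"), y,
                       cfg$bottleneck_expansion, cfg$bottleneck_kernel)
  n_blocks <- if (isTRUE(cfg$use_dense)) cfg$n_dense_blocks else 3L
  for (i in seq_len(n_blocks)) {
    y <- nn_dense_block(ps, sprintf("%s.block%d", pre, i), y, cfg, ctx)
    if (isTRUE(cfg$use_svse))
      y <- nn_svse(ps, sprintf("%s.svse%d", pre, i), y, cfg)
  }
  y <- nn_spatial_sep(ps, paste0(pre, ".spatial"), y, cfg$spatial_out)
  if (isTRUE(cfg$use_svse))
    y <- nn_svse(ps, paste0(pre, ".svse_sp"), y, cfg)
  logits <- nn_head(ps, paste0(pre, ".head"), y, cfg, ctx)
  list(features = y, logits = logits)
}

# ---- exported layer-style surface ---------------------------------------------

#' Inverted bottleneck block
#'
#' Expands the depth by `expansion` with a 1x1 convolution (GELU), applies a
#' depthwise temporal convolution at the expanded depth, and projects back to
#' the input depth with a second 1x1 convolution. Channel and time axes are
#' preserved.
#'
#' @param x array `(D, C, T)` or batched.
#' @param expansion integer >= 1 depth expansion factor.
#' @param kernel temporal kernel of the depthwise stage.
#' @param params,seed see [cse_weights()].
#' @export
inverted_bottleneck <- function(x, expansion = 4L, kernel = 25L, params = NULL,
                                seed = 1L) {
  stopifnot(expansion >= 1)
  module_run(x, function(ps, xn, ctx)
    nn_bottleneck(ps, "bneck", xn, as.integer(expansion), as.integer(kernel)),
    seed = seed, params = params)
}

#' Multi-scale (dense) temporal block
#'
#' Parallel temporal convolutions -- one per entry of `branch_kernels`, each
#' producing `branch_depth` maps followed by GELU -- concatenated depthwise
#' together with the block input when `dense = TRUE` (the dense skip that
#' fuses shallow and deep features).
#'
#' @param x array `(D, C, T)` or batched.
#' @param branch_kernels odd temporal kernel lengths, one per branch.
#' @param branch_depth output maps per branch.
#' @param dense include the input in the concatenation.
#' @param params,seed see [cse_weights()].
#' @export
multiscale_dense_block <- function(x, branch_kernels = c(15L, 25L, 51L, 65L),
                                   branch_depth = 8L, dense = TRUE,
                                   params = NULL, seed = 1L) {
  cfg <- list(branch_kernels = as.integer(branch_kernels),
              branch_depth = as.integer(branch_depth), use_dense = dense,
              variant = "standard")
  module_run(x, function(ps, xn, ctx) nn_dense_block(ps, "block", xn, cfg, ctx),
             seed = seed, params = params)
}

#' Axial depthwise-separable spatial convolution
#'
#' A depthwise C x 1 kernel per feature map collapses the electrode axis to 1,
#' followed by 1x1 pointwise mixing to `d_out` maps and GELU. Output shape is
#' `(d_out, 1, T)`.
#'
#' @param x array `(D, C, T)` or batched.
#' @param d_out pointwise output depth.
#' @param params,seed see [cse_weights()].
#' @export
spatial_depthwise_conv <- function(x, d_out = 16L, params = NULL, seed = 1L) {
  module_run(x, function(ps, xn, ctx)
    nn_spatial_sep(ps, "spatial", xn, as.integer(d_out)),
    seed = seed, params = params)
}

#' DIS-Net forward pass
#'
#' Runs the convolutional branch on a set of epochs: stem, inverted
#' bottleneck, multi-scale dense blocks with svSE, axial spatial convolution
#' with svSE, pooled classification head.
#'
#' @param epochs an [epoch_set] or a `(trials, channels, time)` array of
#'   normalized epochs.
#' @param config a [hafusenet_config()].
#' @param params,seed see [cse_weights()]; `training` toggles dropout /
#'   batch-statistics mode.
#' @param training logical.
#' @return list with `features` (trials x depth x 1 x T pre-pool map) and
#'   `logits` (trials x n_classes); parameters in `attr(, "params")`.
#' @export
disnet_forward <- function(epochs, config = hafusenet_config(), params = NULL,
                           seed = 1L, training = FALSE) {
  x <- epochs_to_tensor(epochs)
  ps <- param_store()
  ctx <- list(training = training)
  run1 <- function() {
    ps_begin(ps)
    xn <- ad_leaf(x)
    if ((config$downsample %||% 1L) > 1L)
      xn <- ad_avgpool_t(xn, config$downsample)
    nn_disnet(ps, "dis", xn, config, ctx)
  }
  set.seed(seed)
  run1()
  if (!is.null(params)) ps_set(ps, params)
  set.seed(sub_seed(seed, 99L)) # dropout stream
  out <- run1()
  res <- list(features = out$features$value, logits = out$logits$value)
  attr(res, "params") <- ps$values
  res
}

# (trials, channels, time) array or epoch_set -> (B, 1, C, T) tensor
epochs_to_tensor <- function(epochs) {
  d <- if (inherits(epochs, "epoch_set")) epochs$data else epochs
  if (length(dim(d)) != 3L) stop("epochs must be a (trials, channels, time) array")
  array(d, dim = c(dim(d)[1], 1L, dim(d)[2], dim(d)[3]))
}
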