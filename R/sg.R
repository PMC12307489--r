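# SG (Separable Ghost) lightweight convolution: a partial standard temporal
# convolution produces round(d_out * ratio) "primary" maps; the remaining
# d_out - round(d_out * ratio) maps are generated cheaply from the primary
# maps by a depthwise 1 x k convolution -> batch norm -> 1x1 pointwise
# convolution -> batch norm -> GELU; all maps are concatenated depthwise so
# the output width is exactly d_out.

nn_sg <- function(ps, name, x, d_out, k, ratio, ctx) {
  if (ratio <= 0 || ratio > 1) stop("sg ratio must be in (0, 1]")
  m <- max(1L, as.integer(round(d_out * ratio)))
  m <- min(m, d_out)
  primary <- nn_conv_t(ps, paste0(name, ".primary"), x, m, k)
  cheap_n <- d_out - m
  if (cheap_n < 1L) return(primary) # ratio = 1 degenerates to a standard conv
  ch <- nn_dwconv_t(ps, paste0(name, ".dw"), primary, k, bias = FALSE)
  ch <- nn_batchnorm(ps, paste0(name, ".bn1"), ch, ctx)
  ch <- nn_conv1x1(ps, paste0(name, ".pw"), ch, cheap_n, bias = FALSE)
  ch <- nn_batchnorm(ps, paste0(name, ".bn2"), ch, ctx)
  ch <- ad_gelu(ch)
  ad_concat_depth(list(primary, ch))
}

# Standard-vs-SG switch used for every "wide" temporal convolution in the
# network; d_out = 1 stays standard (nothing to compress).
nn_temporal_conv <- function(ps, name, x, d_out, k, cfg, ctx) {
  if (identical(cfg$variant, "sg") && d_out > 1L)
    nn_sg(ps, name, x, d_out, k, cfg$sg_ratio %||% 0.5, ctx)
  else
    nn_conv_t(ps, name, x, d_out, k)
}

#' SG (Separable Ghost) convolution module
#'
#' @param x input array `(D_in, C, T)` or batched.
#' @param d_out total output depth; conserved exactly for every ratio.
#' @param ratio compression fraction in (0, 1]: the primary standard
#'   convolution produces `round(d_out * ratio)` maps (floor 1), the cheap
#'   separable path the rest. `ratio = 1` degenerates to a standard
#'   convolution.
#' @param kernel temporal kernel length (default 25: 100 ms at 250 Hz).
#' @param training logical; batch statistics are used for the internal batch
#'   norms when TRUE, running statistics otherwise.
#' @param params,seed see [cse_weights()].
#' @return array `(d_out, C, T)` (or batched); parameters in
#'   `attr(, "params")`.
#' @export
sg_module <- function(x, d_out, ratio = 0.5, kernel = 25L, training = TRUE,
                      params = NULL, seed = 1L) {
  module_run(x, function(ps, xn, ctx)
    nn_sg(ps, "sg", xn, as.integer(d_out), as.integer(kernel), ratio, ctx),
    seed = seed, params = params, training = training)
}

#' Temporal span of a convolution kernel in milliseconds
#'
#' A 1 x k temporal kernel at sampling rate fs spans `k / fs` seconds; the
#' default geometry (k = 25 at 250 Hz) corresponds to a 100 ms analysis
#' window.
#'
#' @param kernel kernel length in samples.
#' @param sampling_rate Hz.
#' @export
kernel_window_ms <- function(kernel, sampling_rate) {
  1000 * kernel / sampling_rate
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in a fitted model, a module output (via
#' its `"params"` attribute), or a plain named list of parameter arrays.
#' Batch-norm running statistics are not trainable and are not counted.
#'
#' @param object a `hafusenet` model, a list of arrays, or an object with a
#'   `"params"` attribute.
#' @return integer count.
#' @export
count_parameters <- function(object) {
  vals <- if (inherits(object, "hafusenet")) {
    object$params
  } else if (!is.null(attr(object, "params"))) {
    attr(object, "params")
  } else if (is.list(object)) {
    object
  } else stop("cannot count parameters of this object")
  if (length(vals) == 0) return(0L)
  as.integer(sum(vapply(vals, length, numeric(1))))
}
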