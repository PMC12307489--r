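# LS-Net (LSTM + SCoT) and the bidirectional C2R / R2C adapters that fuse the
# recurrent branch with DIS-Net along the depth dimension.

# LSTM stack with SCoT after each layer; x: (B, C, T) node -> (B, H, T) node.
nn_lsnet <- function(ps, pre, x, cfg, ctx) {
  h <- cfg$hidden
  y <- x
  for (i in seq_len(cfg$lstm_layers)) {
    y <- nn_lstm_layer(ps, sprintf("%s.l%d", pre, i), y, h)
    if (isTRUE(cfg$use_scot)) {
      d <- dim(y$value)
      f <- ad_reshape(y, c(d[1], 1L, d[2], d[3])) # H treated as channel axis
      f <- nn_scot(ps, sprintf("%s.scot%d", pre, i), f,
                   list(token_mode = cfg$token_mode %||% "pooled",
                        nonlocal_residual = cfg$nonlocal_residual %||% TRUE,
                        cot_kernel = cfg$cot_kernel %||% 3L,
                        allow_depth1 = TRUE))
      y <- ad_reshape(f, d)
    }
  }
  y
}

# C2R: merge (depth, channel) of a (B, D, C, T) map and project to H per step.
nn_c2r <- function(ps, pre, f, hidden) {
  d <- dim(f$value)
  m <- ad_reshape(f, c(d[1], d[2] * d[3], 1L, d[4]))
  m <- nn_conv1x1(ps, paste0(pre, ".proj"), m, hidden)
  ad_reshape(m, c(d[1], hidden, d[4]))
}

# R2C: per-step linear H -> target_depth x target_channels.
nn_r2c <- function(ps, pre, s, target_depth, target_channels) {
  d <- dim(s$value)
  m <- ad_reshape(s, c(d[1], d[2], 1L, d[3]))
  m <- nn_conv1x1(ps, paste0(pre, ".proj"), m, target_depth * target_channels)
  ad_reshape(m, c(d[1], target_depth, target_channels, d[3]))
}

# align temporal lengths by average-pooling the longer map (integer factor)
align_time <- function(a, b) {
  ta <- dim(a$value)[length(dim(a$value))]
  tb <- dim(b$value)[length(dim(b$value))]
  if (ta == tb) return(list(a, b))
  if (ta > tb) {
    if (ta %% tb != 0) stop("temporal lengths are not integer multiples")
    list(ad_avgpool_t(a, ta %/% tb), b)
  } else {
    if (tb %% ta != 0) stop("temporal lengths are not integer multiples")
    list(a, ad_avgpool_t(b, tb %/% ta))
  }
}

# fused head: R2C(ls) ++ dis features -> depthwise separable conv -> head
nn_fuse <- function(ps, pre, dis_f, ls_s, cfg, ctx) {
  d <- dim(ls_s$value)
  ls_f <- nn_r2c(ps, paste0(pre, ".r2c"), ls_s, cfg$r2c_depth,
                 dim(dis_f$value)[3])
  al <- align_time(dis_f, ls_f)
  fused <- ad_concat_depth(al)
  y <- nn_dwconv_t(ps, paste0(pre, ".dw"), fused, cfg$fusion_kernel)
  y <- nn_conv1x1(ps, paste0(pre, ".pw"), y, cfg$fusion_depth)
  y <- ad_gelu(y)
  nn_head(ps, paste0(pre, ".head"), y, cfg, ctx)
}

# whole network; returns logits plus the branch intermediates
nn_hafusenet <- function(ps, x4, cfg, ctx) {
  dis <- nn_disnet(ps, "dis", x4, cfg, ctx)
  if (!isTRUE(cfg$use_lstm))
    return(list(logits = dis$logits, features = dis$features, lsnet = NULL))
  d <- dim(x4$value)
  ls_in <- if (identical(cfg$lsnet_input, "c2r")) {
    nn_c2r(ps, "c2r", dis$features, cfg$hidden)
  } else {
    ad_reshape(x4, c(d[1], d[3], d[4])) # raw C x T epochs
  }
  ls <- nn_lsnet(ps, "ls", ls_in, cfg, ctx)
  logits <- nn_fuse(ps, "fuse", dis$features, ls, cfg, ctx)
  list(logits = logits, features = dis$features, lsnet = ls)
}

softmax_mat <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# ---- exported layer-style surface ---------------------------------------------

#' LS-Net forward pass
#'
#' Stacked LSTM over the time steps of a `C x T` input; after every layer the
#' hidden-state sequence `Y (H x T)` is passed through the SCoT global
#' attention module with H treated as the channel dimension, then fed to the
#' next layer.
#'
#' @param x array `(C, T)` or `(B, C, T)`.
#' @param n_layers,hidden LSTM stack depth and hidden size.
#' @param use_scot apply SCoT between layers (TRUE).
#' @param cot_kernel,token_mode SCoT settings.
#' @param params,seed see [cse_weights()].
#' @return array `(H, T)` (or batched); parameters in `attr(, "params")`.
#' @export
lsnet_forward <- function(x, n_layers = 2L, hidden = 64L, use_scot = TRUE,
                          cot_kernel = 3L, token_mode = "pooled",
                          params = NULL, seed = 1L) {
  if (length(dim(x)) == 2L) {
    batched <- FALSE
    x <- array(x, dim = c(1L, dim(x)))
  } else batched <- TRUE
  cfg <- list(lstm_layers = as.integer(n_layers), hidden = as.integer(hidden),
              use_scot = use_scot, cot_kernel = as.integer(cot_kernel),
              token_mode = token_mode)
  ps <- param_store()
  ctx <- list(training = FALSE)
  set.seed(seed)
  ps_begin(ps)
  nn_lsnet(ps, "ls", ad_leaf(x), cfg, ctx)
  if (!is.null(params)) ps_set(ps, params)
  ps_begin(ps)
  out <- nn_lsnet(ps, "ls", ad_leaf(x), cfg, ctx)
  res <- unbatch(out$value, batched)
  attr(res, "params") <- ps$values
  res
}

#' C2R adapter: feature map to sequence
#'
#' Merges the depth and channel axes of a `(D, C, T)` feature map and applies
#' one linear projection per time step, yielding an `(H, T)` sequence for the
#' recurrent branch. T is preserved.
#'
#' @param f array `(D, C, T)` or batched.
#' @param hidden output feature size H.
#' @param params,seed see [cse_weights()].
#' @export
c2r <- function(f, hidden = 64L, params = NULL, seed = 1L) {
  bx <- as_b4(f)
  ps <- param_store()
  set.seed(seed)
  ps_begin(ps)
  nn_c2r(ps, "c2r", ad_leaf(bx$arr), as.integer(hidden))
  if (!is.null(params)) ps_set(ps, params)
  ps_begin(ps)
  out <- nn_c2r(ps, "c2r", ad_leaf(bx$arr), as.integer(hidden))
  res <- if (bx$batched) out$value else array(out$value, dim(out$value)[-1])
  attr(res, "params") <- ps$values
  res
}

#' R2C adapter: sequence to feature map
#'
#' Applies a per-time-step linear projection from the hidden size H to
#' `target_depth * target_channels` and reshapes to a `(D, C, T)` map, the
#' inverse-direction adapter of [c2r()].
#'
#' @param s array `(H, T)` or `(B, H, T)`.
#' @param target_depth,target_channels output map geometry.
#' @param params,seed see [cse_weights()].
#' @export
r2c <- function(s, target_depth = 8L, target_channels = 22L, params = NULL,
                seed = 1L) {
  if (length(dim(s)) == 2L) {
    batched <- FALSE
    s <- array(s, dim = c(1L, dim(s)))
  } else batched <- TRUE
  ps <- param_store()
  set.seed(seed)
  ps_begin(ps)
  nn_r2c(ps, "r2c", ad_leaf(s), as.integer(target_depth),
         as.integer(target_channels))
  if (!is.null(params)) ps_set(ps, params)
  ps_begin(ps)
  out <- nn_r2c(ps, "r2c", ad_leaf(s), as.integer(target_depth),
                as.integer(target_channels))
  res <- unbatch(out$value, batched)
  attr(res, "params") <- ps$values
  res
}

#' Fuse the two branches and classify
#'
#' Projects the LS-Net sequence back to map form (R2C), concatenates it with
#' the DIS-Net feature map along the depth dimension (average-pooling the
#' longer map when temporal lengths differ), applies a depthwise separable
#' convolution, pooling, flattening and a fully connected Softmax head.
#'
#' @param dis_f DIS-Net feature map, `(D, 1, T)` or batched.
#' @param ls_s LS-Net sequence, `(H, T)` or `(B, H, T)`.
#' @param config a [hafusenet_config()].
#' @param params,seed see [cse_weights()].
#' @return matrix of class probabilities (rows sum to 1); parameters in
#'   `attr(, "params")`.
#' @export
fuse_and_classify <- function(dis_f, ls_s, config = hafusenet_config(),
                              params = NULL, seed = 1L) {
  bf <- as_b4(dis_f)
  if (length(dim(ls_s)) == 2L) ls_s <- array(ls_s, dim = c(1L, dim(ls_s)))
  ps <- param_store()
  ctx <- list(training = FALSE)
  run1 <- function() {
    ps_begin(ps)
    nn_fuse(ps, "fuse", ad_leaf(bf$arr), ad_leaf(ls_s), config, ctx)
  }
  set.seed(seed)
  run1()
  if (!is.null(params)) ps_set(ps, params)
  out <- run1()
  probs <- softmax_mat(out$value)
  attr(probs, "params") <- ps$values
  probs
}

#' Full HA-FuseNet forward pass
#'
#' Runs DIS-Net and LS-Net on the same epochs and fuses them; with
#' `use_lstm = FALSE` in the config the DIS-Net head alone is used.
#'
#' @param epochs an [epoch_set] or `(trials, channels, time)` array.
#' @param config a [hafusenet_config()].
#' @param params,seed see [cse_weights()].
#' @param training logical (dropout and batch-statistics mode).
#' @return `trials x n_classes` matrix of class probabilities; logits in
#'   `attr(, "logits")`, parameters in `attr(, "params")`.
#' @export
hafusenet_forward <- function(epochs, config = hafusenet_config(),
                              params = NULL, seed = 1L, training = FALSE) {
  x <- epochs_to_tensor(epochs)
  ps <- param_store()
  ctx <- list(training = training)
  run1 <- function() {
    ps_begin(ps)
    xn <- ad_leaf(x)
    if ((config$downsample %||% 1L) > 1L)
      xn <- ad_avgpool_t(xn, config$downsample)
    nn_hafusenet(ps, xn, config, ctx)
  }
  set.seed(seed)
  run1()
  if (!is.null(params)) ps_set(ps, params)
  set.seed(sub_seed(seed, 99L))
  out <- run1()
  probs <- softmax_mat(out$logits$value)
  attr(probs, "logits") <- out$logits$value
  attr(probs, "params") <- ps$values
  probs
}
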