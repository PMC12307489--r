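# Thin parameterized layer helpers: each fetches its weights from the shared
# store under a dotted name prefix and returns a tape node.

nn_conv_t <- function(ps, name, x, d_out, k, bias = TRUE) {
  d_in <- dim(x$value)[2]
  w <- ps_get(ps, paste0(name, ".w"), c(d_out, d_in, k), fan_in = d_in * k)
  b <- if (bias) ps_get(ps, paste0(name, ".b"), d_out, init = "zeros", decay = FALSE)
  ad_conv_t(x, w, b)
}

nn_conv1x1 <- function(ps, name, x, d_out, bias = TRUE) {
  nn_conv_t(ps, name, x, d_out, 1L, bias = bias)
}

nn_dwconv_t <- function(ps, name, x, k, bias = TRUE) {
  d <- dim(x$value)[2]
  w <- ps_get(ps, paste0(name, ".w"), c(d, k), fan_in = k)
  y <- ad_dwconv_t(x, w)
  if (bias) {
    b <- ps_get(ps, paste0(name, ".b"), d, init = "zeros", decay = FALSE)
    y <- ad_add(y, ad_reshape(b, c(1L, d, 1L, 1L)))
  }
  y
}

# Depthwise C x 1 spatial kernel collapsing the channel axis to 1.
nn_spconv <- function(ps, name, x, bias = TRUE) {
  d <- dim(x$value)[2]; cc <- dim(x$value)[3]
  w <- ps_get(ps, paste0(name, ".w"), c(d, cc), fan_in = cc)
  b <- if (bias) ps_get(ps, paste0(name, ".b"), d, init = "zeros", decay = FALSE)
  ad_spconv(x, w, b)
}

nn_linear <- function(ps, name, x, d_out, bias = TRUE) {
  d_in <- ncol(x$value)
  w <- ps_get(ps, paste0(name, ".w"), c(d_in, d_out), init = "linear", fan_in = d_in)
  b <- if (bias) ps_get(ps, paste0(name, ".b"), d_out, init = "zeros", decay = FALSE)
  ad_linear(x, w, b)
}

nn_lstm_layer <- function(ps, name, x, hidden) {
  c_in <- dim(x$value)[2]
  # uniform +/- 1/sqrt(H) init, the standard recurrent-layer convention
  lim <- 1 / sqrt(hidden)
  wx <- ps_get(ps, paste0(name, ".wx"), c(c_in, 4L * hidden),
               init = array(stats::runif(c_in * 4 * hidden, -lim, lim),
                            c(c_in, 4L * hidden)))
  wh <- ps_get(ps, paste0(name, ".wh"), c(hidden, 4L * hidden),
               init = array(stats::runif(hidden * 4 * hidden, -lim, lim),
                            c(hidden, 4L * hidden)))
  b <- ps_get(ps, paste0(name, ".b"), 4L * hidden, init = "zeros", decay = FALSE)
  ad_lstm(x, wx, wh, b)
}

nn_batchnorm <- function(ps, name, x, ctx) {
  d <- dim(x$value)[2]
  g <- ps_get(ps, paste0(name, ".gamma"), d, init = "ones", decay = FALSE)
  b <- ps_get(ps, paste0(name, ".beta"), d, init = "zeros", decay = FALSE)
  run <- ps_running(ps, name, d)
  ad_batchnorm(x, g, b, run, isTRUE(ctx$training))
}

# ---- module-runner plumbing for the exported layer-style functions -----------

# Coerce a (D, C, T) or (B, D, C, T) array to batched form.
as_b4 <- function(x) {
  if (length(dim(x)) == 3L) {
    list(arr = array(x, dim = c(1L, dim(x))), batched = FALSE)
  } else if (length(dim(x)) == 4L) {
    list(arr = x, batched = TRUE)
  } else stop("input must be a (D, C, T) or (B, D, C, T) array")
}

unbatch <- function(v, batched) {
  if (batched || is.null(dim(v))) return(v)
  array(v, dim = dim(v)[-1])
}

# Run a parameterized module function on a plain array: initializes parameters
# under `seed`, applies user overrides, runs the forward pass, and attaches
# the realized parameters so callers can hand-chain identical weights.
module_run <- function(x, fn, seed = 1L, params = NULL, training = FALSE) {
  bx <- as_b4(x)
  ps <- param_store()
  ctx <- list(training = training)
  set.seed(seed)
  ps_begin(ps)
  fn(ps, ad_leaf(bx$arr), ctx) # dry run to realize parameter shapes
  if (!is.null(params)) ps_set(ps, params)
  ps_begin(ps)
  out <- fn(ps, ad_leaf(bx$arr), ctx)
  res <- if (ad_is_node(out)) {
    unbatch(out$value, bx$batched)
  } else {
    lapply(out, function(n) unbatch(if (ad_is_node(n)) n$value else n, bx$batched))
  }
  attr(res, "params") <- ps$values
  res
}
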