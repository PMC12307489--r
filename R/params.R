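# Named parameter store shared by all layers. Parameters are created lazily
# on first use (shape inferred at the first forward pass) under whatever RNG
# state is active, so a single set.seed() before building fixes the full
# initialization. Each forward pass binds every parameter to one tape leaf so
# gradients can be collected by name afterwards.

param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$values <- list()    # name -> array
  ps$decay <- list()     # name -> logical (weight decay applies)
  ps$running <- list()   # name -> env(mean, var) for batch norm
  ps$nodes <- list()     # name -> tape leaf for the current forward
  ps
}

ps_begin <- function(ps) {
  ps$nodes <- list()
  invisible(ps)
}

# Fetch (creating if absent) parameter `name` with dims `shape`.
# init: "conv"/"linear" = scaled normal by fan-in, "zeros", "ones",
# or a numeric array used verbatim.
ps_get <- function(ps, name, shape, init = "conv", fan_in = NULL, decay = TRUE) {
  if (is.null(ps$values[[name]])) {
    v <- if (is.numeric(init)) {
      array(init, dim = shape)
    } else if (init == "zeros") {
      array(0, dim = shape)
    } else if (init == "ones") {
      array(1, dim = shape)
    } else {
      if (is.null(fan_in)) fan_in <- prod(shape[-1])
      array(stats::rnorm(prod(shape), sd = sqrt(2 / max(1, fan_in))), dim = shape)
    }
    ps$values[[name]] <- v
    ps$decay[[name]] <- decay
  }
  nd <- ps$nodes[[name]]
  if (is.null(nd)) {
    nd <- ad_leaf(ps$values[[name]], requires = TRUE)
    ps$nodes[[name]] <- nd
  }
  nd
}

# Running statistics container for a batch-norm layer of width d.
ps_running <- function(ps, name, d) {
  r <- ps$running[[name]]
  if (is.null(r)) {
    r <- new.env(parent = emptyenv())
    r$mean <- rep(0, d)
    r$var <- rep(1, d)
    ps$running[[name]] <- r
  }
  r
}

# Collect per-parameter gradients accumulated on the current tape.
ps_grads <- function(ps) {
  out <- list()
  for (name in names(ps$nodes)) {
    g <- ps$nodes[[name]]$grad
    if (is.null(g)) g <- array(0, dim = dim_or1(ps$values[[name]]))
    out[[name]] <- g
  }
  out
}

ps_n_params <- function(ps) {
  sum(vapply(ps$values, length, numeric(1)))
}

# Override stored parameter values by name (used for frozen-weight oracles
# and checkpoint restore).
ps_set <- function(ps, overrides) {
  for (name in names(overrides)) {
    v <- overrides[[name]]
    cur <- ps$values[[name]]
    if (!is.null(cur)) {
      if (length(v) == 1L) v <- array(v, dim = dim_or1(cur)) else dim(v) <- dim_or1(cur)
    }
    ps$values[[name]] <- v
  }
  invisible(ps)
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function() {
  st <- new.env(parent = emptyenv())
  st$m <- list(); st$v <- list(); st$t <- 0L
  st
}

# One Adam update; classic L2 weight decay added to the gradient for
# parameters flagged for decay (weights, not biases or norm affines).
adam_step <- function(ps, grads, st, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (name in names(grads)) {
    g <- grads[[name]]
    if (weight_decay > 0 && isTRUE(ps$decay[[name]]))
      g <- g + weight_decay * ps$values[[name]]
    m <- st$m[[name]]
    v <- st$v[[name]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[name]] <- m
    st$v[[name]] <- v
    ps$values[[name]] <- ps$values[[name]] - lr * (m / b1t) / (sqrt(v / b2t) + eps)
  }
  invisible(ps)
}
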