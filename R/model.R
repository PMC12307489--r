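# The fitting interface: hafusenet() trains the network on an epoch set and
# returns a classed model object with the usual methods.

mi_classes <- function() c("left", "right", "feet", "tongue")

resolve_xy <- function(x, y) {
  if (inherits(x, "epoch_set")) {
    if (is.null(y)) y <- x$labels
    x <- x$data
  }
  if (length(dim(x)) != 3L)
    stop("x must be an epoch_set or a (trials, channels, time) array")
  if (length(y) != dim(x)[1]) stop("labels must match the number of trials")
  if (anyNA(y)) stop("training labels contain NA")
  list(x = x, y = as.integer(y))
}

# one full forward on a tape; returns list(loss node, logits node)
forward_loss <- function(ps, xb, yb, cfg, ctx) {
  ps_begin(ps)
  xn <- ad_leaf(xb)
  if ((cfg$downsample %||% 1L) > 1L) xn <- ad_avgpool_t(xn, cfg$downsample)
  out <- nn_hafusenet(ps, xn, cfg, ctx)
  loss <- ad_softmax_xent(out$logits, yb + 1L)
  list(loss = loss, logits = out$logits)
}

#' Fit HA-FuseNet
#'
#' Trains the full network (or any ablation variant selected in the config)
#' with Adam on categorical cross-entropy. One master seed is fanned out to
#' parameter initialization, minibatch order and dropout, so identical seeds
#' reproduce identical training histories bit for bit.
#'
#' @param x an [epoch_set] of normalized epochs, or a
#'   `(trials, channels, time)` array.
#' @param y integer class labels 0--3 (taken from the epoch set when omitted).
#' @param config a [hafusenet_config()].
#' @param train a [train_config()].
#' @return an object of class `"hafusenet"` with methods `print`, `summary`,
#'   `predict`, `plot` (training curves) and `coef` (parameter arrays).
#'   `$history` holds one row per epoch (mean minibatch loss and training
#'   accuracy).
#' @examples
#' cfg <- synth_config(n_subjects = 1, n_trials_per_class = 4)
#' ep <- generate_epochset(cfg, "S01")
#' fit <- hafusenet(ep, config = hafusenet_config("desk"),
#'                  train = train_config(epochs = 2, verbose = 0))
#' predict(fit, ep, type = "class")
#' @export
hafusenet <- function(x, y = NULL, config = hafusenet_config(),
                      train = train_config()) {
  xy <- resolve_xy(x, y)
  model <- build_hafusenet(dim(xy$x)[2:3], config, seed = train$seed)
  train_model(model, xy$x, xy$y, train)
}

#' Initialize an untrained model
#'
#' Builds and initializes all parameters for the given epoch geometry without
#' training (useful for parameter counting and ablation construction).
#'
#' @param input_dim `(channels, time)` of the epochs the model will see.
#' @param config a [hafusenet_config()].
#' @param seed initialization seed.
#' @export
build_hafusenet <- function(input_dim, config = hafusenet_config(), seed = 1L) {
  ps <- param_store()
  set.seed(sub_seed(seed, 1L))
  dummy <- array(0, dim = c(1L, input_dim[1], input_dim[2]))
  forward_loss(ps, epochs_to_tensor(dummy), 0L, config,
               list(training = FALSE))
  structure(list(params = ps$values, decay = ps$decay,
                 running = lapply(ps$running, function(r)
                   list(mean = r$mean, var = r$var)),
                 config = config, input_dim = input_dim,
                 classes = mi_classes()[seq_len(config$n_classes)],
                 history = NULL, seed = seed,
                 n_params = ps_n_params(ps)),
            class = "hafusenet")
}

ps_from_model <- function(model) {
  ps <- param_store()
  ps$values <- model$params
  ps$decay <- model$decay
  for (nm in names(model$running)) {
    r <- new.env(parent = emptyenv())
    r$mean <- model$running[[nm]]$mean
    r$var <- model$running[[nm]]$var
    ps$running[[nm]] <- r
  }
  ps
}

#' Train (or continue training) a model
#'
#' Minibatch Adam on categorical cross-entropy at the configured learning
#' rate, weight decay, batch size and epoch count. Aborts with diagnostics if
#' the loss becomes non-finite.
#'
#' @param model a `"hafusenet"` object (possibly untrained, from
#'   [build_hafusenet()]).
#' @param x,y training epochs and 0-based labels (or an [epoch_set] and NULL).
#' @param train a [train_config()].
#' @return the trained model with `$history` extended.
#' @export
train_model <- function(model, x, y = NULL, train = train_config()) {
  xy <- resolve_xy(x, y)
  x <- xy$x; y <- xy$y
  cfg <- model$config
  ps <- ps_from_model(model)
  opt <- adam_init()
  n <- dim(x)[1]
  val_idx <- integer(0)
  set.seed(sub_seed(train$seed, 2L))
  if (train$val_fraction > 0) {
    val_idx <- sample(n, max(1L, round(train$val_fraction * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  hist <- vector("list", train$epochs)
  ctx <- list(training = TRUE)
  for (ep in seq_len(train$epochs)) {
    ord <- sample(tr_idx)
    losses <- c(); correct <- 0L
    for (start in seq(1L, length(ord), by = train$batch_size)) {
      idx <- ord[start:min(start + train$batch_size - 1L, length(ord))]
      xb <- epochs_to_tensor(x[idx, , , drop = FALSE])
      fw <- forward_loss(ps, xb, y[idx], cfg, ctx)
      lv <- as.numeric(fw$loss$value)
      if (!is.finite(lv))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                     ep, start),
             "check learning rate / input scaling")
      losses <- c(losses, lv)
      correct <- correct + sum(max.col(fw$logits$value,
                                       ties.method = "first") == y[idx] + 1L)
      ad_backward(fw$loss)
      adam_step(ps, ps_grads(ps), opt, lr = train$learning_rate,
                weight_decay = train$weight_decay)
    }
    row <- data.frame(epoch = ep, loss = mean(losses),
                      accuracy = correct / length(ord))
    if (length(val_idx)) {
      pv <- predict_core(ps, x[val_idx, , , drop = FALSE], cfg)
      row$val_accuracy <- mean(max.col(pv, ties.method = "first") ==
                                 y[val_idx] + 1L)
    }
    hist[[ep]] <- row
    if (train$verbose > 0 && ep %% train$verbose == 0)
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, row$loss,
                      row$accuracy))
  }
  model$params <- ps$values
  model$running <- lapply(ps$running, function(r) list(mean = r$mean,
                                                       var = r$var))
  newh <- do.call(rbind, hist)
  model$history <- if (is.null(model$history)) newh else {
    newh$epoch <- newh$epoch + max(model$history$epoch)
    rbind(model$history, newh)
  }
  model$train <- train
  model
}

predict_core <- function(ps, x, cfg, batch_size = 64L) {
  n <- dim(x)[1]
  probs <- matrix(0, n, cfg$n_classes)
  ctx <- list(training = FALSE)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    ps_begin(ps)
    xn <- ad_leaf(epochs_to_tensor(x[idx, , , drop = FALSE]))
    if ((cfg$downsample %||% 1L) > 1L) xn <- ad_avgpool_t(xn, cfg$downsample)
    out <- nn_hafusenet(ps, xn, cfg, ctx)
    probs[idx, ] <- softmax_mat(out$logits$value)
  }
  probs
}

#' @export
predict.hafusenet <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "epoch_set")) newdata <- newdata$data
  if (length(dim(newdata)) != 3L)
    stop("newdata must be an epoch_set or (trials, channels, time) array")
  ps <- ps_from_model(object)
  probs <- predict_core(ps, newdata, object$config)
  colnames(probs) <- object$classes
  if (type == "prob") probs
  else factor(object$classes[max.col(probs, ties.method = "first")],
              levels = object$classes)
}

#' Evaluate a fitted model on labeled epochs
#'
#' @param model a `"hafusenet"` object.
#' @param epochs a labeled [epoch_set].
#' @return list with `accuracy`, `kappa` and the `confusion` matrix.
#' @export
evaluate_model <- function(model, epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  pred <- as.integer(predict(model, epochs, type = "class")) - 1L
  cm <- confusion_matrix(epochs$labels, pred, model$config$n_classes)
  list(accuracy = mean(pred == epochs$labels), kappa = kappa_score(cm),
       confusion = cm)
}

#' @export
print.hafusenet <- function(x, ...) {
  cfg <- x$config
  variant <- paste0(if (identical(cfg$variant, "sg")) "SG " else "",
                    if (isTRUE(cfg$use_lstm))
                      if (isTRUE(cfg$use_scot)) "DIS+LSTM+SCoT" else "DIS+LSTM"
                    else if (isTRUE(cfg$use_svse)) "DI+svSE"
                    else if (isTRUE(cfg$use_dense)) "BI+Dense"
                    else if (isTRUE(cfg$use_bottleneck)) "Base-Inception"
                    else "Inception")
  cat(sprintf("HA-FuseNet [%s, %s scale]: %d trainable parameters\n",
              variant, cfg$scale, x$n_params))
  cat(sprintf("input %d channels x %d samples, %d classes (%s)\n",
              x$input_dim[1], x$input_dim[2], cfg$n_classes,
              paste(x$classes, collapse = ", ")))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("trained %d epochs: final loss %.4f, training accuracy %.1f%%\n",
                nrow(x$history), last$loss, 100 * last$accuracy))
  } else cat("untrained\n")
  invisible(x)
}

#' @export
summary.hafusenet <- function(object, ...) {
  print(object)
  cat("\nconfig:\n")
  cfg <- object$config
  for (nm in setdiff(names(cfg), "scale"))
    cat(sprintf("  %-22s %s\n", nm, paste(format(cfg[[nm]]), collapse = " ")))
  if (!is.null(object$history)) {
    cat("\nhistory (last 5 epochs):\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.hafusenet <- function(object, ...) object$params

#' @export
plot.hafusenet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  plot(h$epoch, h$accuracy, type = "l", ylim = c(0, 1), xlab = "epoch",
       ylab = "accuracy", main = "training accuracy", ...)
  if (!is.null(h$val_accuracy))
    graphics::lines(h$epoch, h$val_accuracy, lty = 2)
  invisible(x)
}
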