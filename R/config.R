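#' Model configuration for HA-FuseNet
#'
#' Collects every architectural hyperparameter and the ablation switches. Two
#' size presets are provided: `"full"` (the full-size architecture: 250 Hz
#' input, 1 x 25 stem kernel spanning 100 ms, branch kernels bracketing mu/beta
#' cycle lengths, LSTM hidden size 64) and `"desk"`, a scaled-down geometry
#' (about 5 x 10^4 parameters) that trains in minutes on one CPU and is used
#' throughout the test-suite and synthetic-data evaluations.
#'
#' @param scale `"full"` or `"desk"`.
#' @param ... named overrides of any listed field.
#' @return a list of class `"hafusenet_config"`.
#' @details Fields (defaults for `"full"` / `"desk"`):
#' \describe{
#'   \item{n_classes}{number of motor-imagery classes (4).}
#'   \item{downsample}{input temporal average-pooling factor applied before
#'     both branches (1 / 10). The desk preset decimates 250 Hz epochs to an
#'     effective 25 Hz, which retains most of the mu-band power contrast that
#'     carries the class signal while cutting compute by the same factor.}
#'   \item{stem_depth, stem_kernel}{stem temporal convolution (8, 25 / 6, 5).}
#'   \item{bottleneck_expansion, bottleneck_kernel}{inverted bottleneck
#'     (4, 25 / 2, 5).}
#'   \item{branch_kernels}{temporal kernels of the multi-scale block branches,
#'     all odd; (15, 25, 51, 65) samples at 250 Hz = 60--260 ms / (3, 5, 9)
#'     at the decimated rate = 120--360 ms.}
#'   \item{branch_depth}{maps per branch (8 / 4).}
#'   \item{n_dense_blocks}{multi-scale dense blocks in the final model (2).}
#'   \item{spatial_out}{depth after the axial depthwise-separable spatial
#'     convolution (16 / 24).}
#'   \item{pool}{average-pooling width of the classification heads (75 / 15).}
#'   \item{dropout}{dropout before the fully connected layers (0.25).}
#'   \item{svse_reduction}{cSE reduction ratio r (2).}
#'   \item{svse_residual}{add a residual copy of the input around each svSE
#'     stage (TRUE); keeps activation scale stable through stacked
#'     Softmax-normalized gates.}
#'   \item{lstm_layers, hidden}{LS-Net depth and hidden size (2, 64 / 2, 40).}
#'   \item{lsnet_input}{`"raw"` (epochs C x T feed the LSTM) or `"c2r"`
#'     (the post-bottleneck DIS feature map is projected in).}
#'   \item{cot_kernel, token_mode, nonlocal_residual}{SCoT settings.}
#'   \item{r2c_depth}{depth of the LS branch after R2C, concatenated onto the
#'     DIS features (8).}
#'   \item{fusion_kernel, fusion_depth}{fused-head depthwise-separable
#'     convolution (15, 24 / 3, 32).}
#'   \item{fc_hidden}{optional hidden width of the fused classifier (0 = none /
#'     64).}
#'   \item{use_bottleneck, use_dense, use_svse, use_lstm, use_scot}{ablation
#'     switches; see [hafusenet_variant()].}
#'   \item{variant, sg_ratio}{`"standard"` or `"sg"` temporal convolutions and
#'     the SG compression ratio (0.5).}
#' }
#' @export
hafusenet_config <- function(scale = c("desk", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    scale = scale,
    n_classes = 4L,
    downsample = 1L,
    stem_depth = 8L, stem_kernel = 25L,
    bottleneck_expansion = 4L, bottleneck_kernel = 25L,
    branch_kernels = c(15L, 25L, 51L, 65L),
    branch_depth = 8L,
    n_dense_blocks = 2L,
    spatial_out = 16L,
    pool = 75L,
    dropout = 0.25,
    svse_reduction = 2L,
    svse_residual = TRUE,
    lstm_layers = 2L, hidden = 64L,
    lsnet_input = "raw",
    cot_kernel = 3L, token_mode = "pooled", nonlocal_residual = TRUE,
    r2c_depth = 8L,
    fusion_kernel = 15L, fusion_depth = 24L,
    fc_hidden = 0L,
    use_bottleneck = TRUE, use_dense = TRUE, use_svse = TRUE,
    use_lstm = TRUE, use_scot = TRUE,
    variant = "standard", sg_ratio = 0.5
  )
  if (scale == "desk") {
    cfg$downsample <- 10L
    cfg$stem_depth <- 6L; cfg$stem_kernel <- 5L
    cfg$bottleneck_expansion <- 2L; cfg$bottleneck_kernel <- 5L
    cfg$branch_kernels <- c(3L, 5L, 9L)
    cfg$branch_depth <- 4L
    cfg$spatial_out <- 24L
    cfg$pool <- 15L
    cfg$hidden <- 40L
    cfg$fusion_kernel <- 3L; cfg$fusion_depth <- 32L
    cfg$fc_hidden <- 64L
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  if (any(cfg$branch_kernels %% 2 == 0)) stop("branch kernels must be odd")
  if (cfg$n_classes < 2) stop("n_classes must be >= 2")
  if (cfg$variant == "sg" &&
      (cfg$sg_ratio <= 0 || cfg$sg_ratio > 1)) stop("sg_ratio must be in (0, 1]")
  class(cfg) <- "hafusenet_config"
  cfg
}

#' Ablation-family configurations
#'
#' Builds the six ablation variants of the model family from switch settings:
#' `"inception"` (3 plain multi-scale blocks), `"base_inception"` (+ inverted
#' bottleneck), `"bi_dense"` (+ dense skips, 2 blocks), `"di_svse"` (+ svSE),
#' `"dis_lstm"` (+ LSTM branch, no SCoT), `"hafusenet"` (full model,
#' + SCoT).
#'
#' @param name one of the six variant names above.
#' @param scale,... passed to [hafusenet_config()].
#' @export
hafusenet_variant <- function(name = c("hafusenet", "inception",
                                       "base_inception", "bi_dense",
                                       "di_svse", "dis_lstm"),
                              scale = "desk", ...) {
  name <- match.arg(name)
  sw <- switch(name,
    inception      = list(use_bottleneck = FALSE, use_dense = FALSE,
                          use_svse = FALSE, use_lstm = FALSE, use_scot = FALSE),
    base_inception = list(use_bottleneck = TRUE, use_dense = FALSE,
                          use_svse = FALSE, use_lstm = FALSE, use_scot = FALSE),
    bi_dense       = list(use_bottleneck = TRUE, use_dense = TRUE,
                          use_svse = FALSE, use_lstm = FALSE, use_scot = FALSE),
    di_svse        = list(use_bottleneck = TRUE, use_dense = TRUE,
                          use_svse = TRUE, use_lstm = FALSE, use_scot = FALSE),
    dis_lstm       = list(use_bottleneck = TRUE, use_dense = TRUE,
                          use_svse = TRUE, use_lstm = TRUE, use_scot = FALSE),
    hafusenet      = list(use_bottleneck = TRUE, use_dense = TRUE,
                          use_svse = TRUE, use_lstm = TRUE, use_scot = TRUE))
  do.call(hafusenet_config, c(list(scale = scale), sw, list(...)))
}

#' Training configuration
#'
#' @param batch_size minibatch size (32).
#' @param epochs training epochs (300 at full scale; tests use fewer).
#' @param learning_rate initial Adam learning rate (1e-3).
#' @param weight_decay L2 coefficient added to weight gradients (5e-3).
#' @param seed master seed fanned out to initialization, data order and
#'   dropout streams.
#' @param val_fraction held-out fraction carved from the training set for
#'   monitoring; 0 disables (default -- training runs a fixed epoch count).
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @export
train_config <- function(batch_size = 32L, epochs = 300L, learning_rate = 1e-3,
                         weight_decay = 5e-3, seed = 1L, val_fraction = 0,
                         verbose = 0L) {
  stopifnot(batch_size >= 1, epochs >= 1, learning_rate > 0, weight_decay >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed), val_fraction = val_fraction,
                 verbose = as.integer(verbose)),
            class = "hafusenet_train_config")
}

# deterministic sub-seed fan-out, kept inside 32-bit range
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Read / write configurations as YAML
#'
#' @param path YAML file. Sections `model:` and `train:` map onto
#'   [hafusenet_config()] and [train_config()]; a `synth:` section maps onto
#'   [synth_config()].
#' @return a named list with any of `model`, `train`, `synth` entries.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$model)) {
    sc <- y$model$scale %||% "desk"
    y$model$scale <- NULL
    out$model <- do.call(hafusenet_config, c(list(scale = sc), y$model))
  }
  if (!is.null(y$train)) out$train <- do.call(train_config, y$train)
  if (!is.null(y$synth)) out$synth <- do.call(synth_config, y$synth)
  out
}
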