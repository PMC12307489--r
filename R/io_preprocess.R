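# Reading, cleaning, epoching and normalizing BCI-IV-2A-style recordings.
# Continuous signals are carried in microvolts as channels x samples matrices;
# motor-imagery epochs are cut from 1 s to 4 s after the cue (half-open, so a
# 3 s x sampling-rate window exactly) and z-scored per trial and channel.

#' Continuous recording container
#'
#' @param signal channels x samples numeric matrix (microvolts).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector; labels starting with `"EOG"` are
#'   tagged as ocular channels.
#' @param events data.frame with integer columns `onset` (0-based sample) and
#'   `code`.
#' @param subject_id,session identifiers (session `"T"` train / `"E"` eval).
#' @return object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sampling_rate, channel_labels,
                          events = data.frame(onset = integer(0),
                                              code = integer(0)),
                          subject_id = "S01", session = "T") {
  stopifnot(is.matrix(signal), sampling_rate > 0,
            length(channel_labels) == nrow(signal))
  if (nrow(events) && (any(events$onset < 0) ||
                       any(events$onset >= ncol(signal))))
    stop("event onsets must lie within [0, samples)")
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 modality = ifelse(startsWith(toupper(channel_labels), "EOG"),
                                   "EOG", "EEG"),
                 events = events[order(events$onset), , drop = FALSE],
                 subject_id = subject_id, session = session),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s session %s: %d channels (%d EEG) x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$session, nrow(x$signal),
              sum(x$modality == "EEG"), ncol(x$signal), x$sampling_rate,
              nrow(x$events)))
  invisible(x)
}

#' Read a GDF recording, keeping EEG channels only
#'
#' Parses a GDF 1.x file, tags channel modality from the labels, and drops
#' EOG channels, returning the EEG-only continuous recording with its event
#' annotations in onset order.
#'
#' @param path GDF file.
#' @param subject_id,session identifiers attached to the recording; guessed
#'   from the file name (`A01T.gdf` style) when NULL.
#' @return a [raw_recording] containing only EEG-modality channels.
#' @export
read_recording <- function(path, subject_id = NULL, session = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- read_gdf(path)
  base <- sub("\\.gdf$", "", basename(path), ignore.case = TRUE)
  if (is.null(subject_id))
    subject_id <- if (grepl("^A\\d+[TE]$", base)) substr(base, 1, nchar(base) - 1) else base
  if (is.null(session))
    session <- if (grepl("[TE]$", base)) substring(base, nchar(base)) else "T"
  eeg <- !startsWith(toupper(g$channel_labels), "EOG")
  if (!any(eeg)) stop("no EEG channels remain after excluding EOG")
  raw_recording(g$signal[eeg, , drop = FALSE], g$sampling_rate,
                g$channel_labels[eeg], g$events, subject_id, session)
}

#' Channel-wise mean imputation of missing samples
#'
#' Replaces every NaN/NA sample by the mean of that channel's non-missing
#' samples; non-missing samples are untouched, so the operation is idempotent.
#'
#' @param rec a [raw_recording].
#' @return the recording with a gap-free signal.
#' @export
impute_missing <- function(rec) {
  sig <- rec$signal
  bad <- is.na(sig)
  if (!any(bad)) return(rec)
  for (ch in which(rowSums(bad) > 0)) {
    ok <- !bad[ch, ]
    if (!any(ok)) stop("channel ", rec$channel_labels[ch],
                       " is entirely missing; mean is undefined")
    sig[ch, !ok] <- mean(sig[ch, ok])
  }
  rec$signal <- sig
  rec
}

#' Trial epochs container
#'
#' @param data trials x channels x time array.
#' @param labels integer per-trial class, 0--3 (left hand, right hand, feet,
#'   tongue); may be NA for unlabeled evaluation epochs.
#' @param subject_id,session identifiers.
#' @param fs sampling rate (Hz).
#' @param window cue-relative `(start, end)` seconds.
#' @export
epoch_set <- function(data, labels, subject_id = "S01", session = "T",
                      fs = 250, window = c(1, 4)) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels))
  structure(list(data = data, labels = as.integer(labels),
                 subject_id = subject_id, session = session, fs = fs,
                 window = window),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s session %s: %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              x$subject_id, x$session, d[1], d[2], d[3], x$fs,
              x$window[1], x$window[2]))
  if (d[1]) {
    tb <- table(factor(x$labels, levels = 0:3,
                       labels = c("left", "right", "feet", "tongue")))
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# default BCI-IV-2A cue codes: 769..772 = left, right, feet, tongue
default_code_map <- function() c("769" = 0L, "770" = 1L, "771" = 2L, "772" = 3L)

#' Cut cue-locked motor-imagery epochs
#'
#' One epoch per task event, spanning the half-open window
#' `[cue + window[1], cue + window[2])` seconds (default 1 s to 4 s after the
#' cue, i.e. exactly 3 s x sampling-rate samples). Events whose window runs
#' past the end of the recording are dropped with a warning. Labels come from
#' `code_map` (training sessions) or from `labels` (evaluation sessions, see
#' [load_eval_labels()]).
#'
#' @param rec a cleaned [raw_recording].
#' @param task_codes event codes identifying the motor-imagery cues.
#' @param window cue-relative seconds `(start, end)`.
#' @param labels optional integer vector (0--3), one per task event, used when
#'   the recording itself carries no class information.
#' @param code_map named integer vector mapping event code -> class 0--3.
#' @return an [epoch_set].
#' @export
extract_epochs <- function(rec, task_codes = as.integer(names(default_code_map())),
                           window = c(1, 4), labels = NULL,
                           code_map = default_code_map()) {
  if (any(is.na(rec$signal)))
    stop("recording contains missing values; run impute_missing() first")
  fs <- rec$sampling_rate
  ev <- rec$events[rec$events$code %in% task_codes, , drop = FALSE]
  len <- as.integer(round((window[2] - window[1]) * fs))
  start <- ev$onset + as.integer(round(window[1] * fs))
  keep <- start >= 0 & (start + len) <= ncol(rec$signal)
  if (!is.null(labels)) {
    if (length(labels) != nrow(ev))
      stop(sprintf("label vector length (%d) does not match task event count (%d)",
                   length(labels), nrow(ev)))
    lab <- as.integer(labels)
  } else {
    lab <- unname(code_map[as.character(ev$code)])
  }
  if (any(!keep)) {
    warning(sum(!keep), " event(s) dropped: epoch window exceeds the recording")
    start <- start[keep]; lab <- lab[keep]
  }
  n <- length(start)
  cdim <- nrow(rec$signal)
  data <- array(0, dim = c(n, cdim, len))
  for (i in seq_len(n))
    data[i, , ] <- rec$signal[, (start[i] + 1L):(start[i] + len), drop = FALSE]
  epoch_set(data, if (n) lab else integer(0), rec$subject_id, rec$session,
            fs, window)
}

#' Load evaluation-session class labels from a MAT file
#'
#' Reads the per-trial class vector (`classlabel` by convention, else the
#' first numeric variable) from a MAT v4 file and re-indexes the 1-based
#' classes to 0--3.
#'
#' @param path MAT file.
#' @param n_expected optional epoch count for a consistency check.
#' @return integer vector of class labels 0--3.
#' @export
load_eval_labels <- function(path, n_expected = NULL) {
  vars <- read_mat_v4(path)
  v <- vars[["classlabel"]] %||% vars[[1]]
  if (is.null(v)) stop("no numeric label variable found in ", path)
  lab <- as.integer(round(as.numeric(v))) - 1L
  if (length(lab) && (min(lab) < 0 || max(lab) > 3))
    stop("class labels outside 1..4 in ", path)
  if (!is.null(n_expected) && length(lab) != n_expected)
    stop(sprintf("label count (%d) does not match epoch count (%d)",
                 length(lab), n_expected))
  lab
}

#' Normalize epochs
#'
#' Z-score (`x' = (x - mu) / sigma`, population sigma) or min--max
#' (`x' = (x - min) / (max - min)`, mapping onto [0, 1]) normalization.
#' Statistics are computed per trial and channel over the time axis by
#' default (`scope = "trial_channel"`), or per channel over the whole session
#' (`scope = "channel_session"`). Groups with sigma (or range) below
#' `epsilon` are mapped to zeros.
#'
#' @param epochs an [epoch_set].
#' @param method `"zscore"` (default) or `"minmax"`.
#' @param scope normalization grouping.
#' @param epsilon degeneracy guard (> 0).
#' @return the normalized [epoch_set].
#' @export
normalize_epochs <- function(epochs, method = c("zscore", "minmax"),
                             scope = c("trial_channel", "channel_session"),
                             epsilon = 1e-8) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  stopifnot(epsilon > 0)
  x <- epochs$data
  d <- dim(x)
  if (d[1] == 0) return(epochs)
  if (scope == "trial_channel") {
    if (method == "zscore") {
      mu <- rowMeans(x, dims = 2L)
      sg <- sqrt(pmax(0, rowMeans(x * x, dims = 2L) - mu * mu))
      keep <- sg >= epsilon
      xc <- x - array(mu, dim = d)
      sc <- array(ifelse(keep, sg, Inf), dim = d)
      x <- xc / sc
    } else {
      lo <- apply(x, c(1, 2), min)
      hi <- apply(x, c(1, 2), max)
      rg <- hi - lo
      rg[rg < epsilon] <- Inf
      x <- (x - array(lo, dim = d)) / array(rg, dim = d)
    }
  } else {
    # per channel across all trials and samples
    for (ch in seq_len(d[2])) {
      v <- x[, ch, ]
      if (method == "zscore") {
        mu <- mean(v); sg <- sqrt(mean((v - mu)^2))
        x[, ch, ] <- if (sg < epsilon) 0 else (v - mu) / sg
      } else {
        lo <- min(v); rg <- max(v) - lo
        x[, ch, ] <- if (rg < epsilon) 0 else (v - lo) / rg
      }
    }
  }
  epochs$data <- x
  epochs
}

#' Save / load an epoch cache
#'
#' Epoch caches are stored with R native serialization, carrying the data
#' array, labels and the subject / session / sampling-rate / window metadata.
#'
#' @param epochs an [epoch_set].
#' @param path cache file (conventionally `.rds`).
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(unclass(epochs), path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  obj <- readRDS(path)
  epoch_set(obj$data, obj$labels, obj$subject_id, obj$session, obj$fs,
            obj$window)
}

# concatenate epoch sets (cross-subject training pools)
combine_epochs <- function(sets) {
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$data)
  n <- sum(vapply(sets, function(s) dim(s$data)[1], numeric(1)))
  data <- array(0, dim = c(n, d[2], d[3]))
  labels <- integer(n)
  off <- 0L
  for (s in sets) {
    k <- dim(s$data)[1]
    if (k) {
      data[off + seq_len(k), , ] <- s$data
      labels[off + seq_len(k)] <- s$labels
    }
    off <- off + k
  }
  epoch_set(data, labels,
            paste(unique(vapply(sets, `[[`, "", "subject_id")), collapse = "+"),
            sets[[1]]$session, sets[[1]]$fs, sets[[1]]$window)
}
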