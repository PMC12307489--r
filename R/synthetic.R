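# Synthetic 4-class, 22-channel motor-imagery EEG. Continuous recordings are
# 1/f-shaped background noise plus narrowband mu/beta oscillations on
# class-specific (lateralized) channels whose amplitude is multiplicatively
# attenuated during each matching trial's imagery window -- an ERD analogue
# with a 0.5 s linear ramp. Per-subject variability enters as log-normal
# channel gains. Everything is deterministic given (seed, subject, session).

#' Synthetic recording configuration
#'
#' @param n_subjects number of subjects the study emulates (9).
#' @param n_trials_per_class trials per class and session (20, i.e. 80 trials
#'   per recording).
#' @param sampling_rate Hz (250).
#' @param n_channels electrode count (22).
#' @param class_profiles list of 4 profiles, each
#'   `list(channels =, freq =, bandwidth =, amplitude =, attenuation =)`:
#'   the oscillation carried by those channels and the multiplicative ERD
#'   factor in (0, 1] applied during matching trials (1 = no modulation,
#'   smaller = stronger desynchronization). Defaults place mu-band (10 Hz)
#'   rhythms on disjoint channel pairs around the C3/Cz/C4 motor strip
#'   positions of the standard 22-electrode montage, attenuation 0.3.
#' @param noise_sd background 1/f noise scale, microvolts (2).
#' @param subject_shift_sd log-normal sd of per-subject channel gains (0.1).
#' @param trial_sec trial cycle length, seconds (6; cue at cycle start,
#'   imagery window attenuated over `[cue + 0.5 s, cue + 4 s]`).
#' @param lead_in_sec pre-task recording, seconds (2).
#' @param seed integer; fixes the full output bit-stream together with the
#'   subject id and session.
#' @export
synth_config <- function(n_subjects = 9L, n_trials_per_class = 20L,
                         sampling_rate = 250, n_channels = 22L,
                         class_profiles = NULL, noise_sd = 2,
                         subject_shift_sd = 0.1, trial_sec = 6,
                         lead_in_sec = 2, seed = 1L) {
  if (is.null(class_profiles)) {
    # right-hemisphere channels for left hand, left-hemisphere for right hand,
    # midline for feet, posterior pair for tongue (22-channel 2A montage rows)
    class_profiles <- list(
      left   = list(channels = c(12L, 13L), freq = 10, bandwidth = 1,
                    amplitude = 8, attenuation = 0.3),
      right  = list(channels = c(7L, 8L),   freq = 10, bandwidth = 1,
                    amplitude = 8, attenuation = 0.3),
      feet   = list(channels = c(9L, 10L),  freq = 10, bandwidth = 1,
                    amplitude = 8, attenuation = 0.3),
      tongue = list(channels = c(17L, 18L), freq = 10, bandwidth = 1,
                    amplitude = 8, attenuation = 0.3))
  }
  stopifnot(length(class_profiles) == 4L, noise_sd >= 0,
            subject_shift_sd >= 0)
  for (p in class_profiles) {
    if (p$attenuation <= 0 || p$attenuation > 1)
      stop("attenuation factors must lie in (0, 1]")
    if (any(p$channels > n_channels)) stop("profile channel out of range")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_class = as.integer(n_trials_per_class),
                 sampling_rate = sampling_rate,
                 n_channels = as.integer(n_channels),
                 class_profiles = class_profiles, noise_sd = noise_sd,
                 subject_shift_sd = subject_shift_sd, trial_sec = trial_sec,
                 lead_in_sec = lead_in_sec, seed = as.integer(seed)),
            class = "synth_config")
}

# 1/f-amplitude ("pink") noise of length n, unit variance, via FFT shaping
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) # two-sided frequency index
  shape <- c(0, 1 / sqrt(freq[-1]))
  v <- Re(stats::fft(f * shape, inverse = TRUE)) / n
  v / stats::sd(v)
}

#' Generate one synthetic continuous recording
#'
#' @param cfg a [synth_config()].
#' @param subject_id e.g. `"S01"`.
#' @param session `"T"` or `"E"` (different random stream per session).
#' @return a [raw_recording] with 2A-style cue event codes 769--772.
#' @export
generate_recording <- function(cfg, subject_id = "S01", session = "T") {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sampling_rate
  set.seed(sub_seed(cfg$seed,
                    sum(utf8ToInt(paste0(subject_id, session)))))
  n_trials <- 4L * cfg$n_trials_per_class
  labels <- sample(rep(0:3, cfg$n_trials_per_class))
  total_sec <- cfg$lead_in_sec + n_trials * cfg$trial_sec + 1
  ns <- as.integer(ceiling(total_sec * fs / fs) * fs) # whole-second records
  gains <- exp(stats::rnorm(cfg$n_channels, 0, cfg$subject_shift_sd))
  cues <- as.integer(cfg$lead_in_sec * fs + (seq_len(n_trials) - 1L) *
                       cfg$trial_sec * fs)
  sig <- matrix(0, cfg$n_channels, ns)
  for (ch in seq_len(cfg$n_channels)) sig[ch, ] <- cfg$noise_sd * pink_noise(ns)
  tidx <- seq_len(ns)
  ramp_n <- as.integer(0.5 * fs)
  for (k in seq_along(cfg$class_profiles)) {
    p <- cfg$class_profiles[[k]]
    env <- rep(1, ns)
    if (p$attenuation < 1) {
      att <- p$attenuation
      for (tr in which(labels == (k - 1L))) {
        on <- cues[tr] + as.integer(0.5 * fs)   # ERD onset: cue + 0.5 s
        off <- cues[tr] + as.integer(4 * fs)    # release: cue + 4 s
        dn <- on + seq_len(ramp_n)
        env[dn] <- 1 + (att - 1) * seq_len(ramp_n) / ramp_n
        env[(on + ramp_n + 1L):off] <- att
        up <- off + seq_len(ramp_n)
        up <- up[up <= ns]
        env[up] <- att + (1 - att) * seq_along(up) / ramp_n
      }
    }
    for (ch in p$channels) {
      drift <- cumsum(stats::rnorm(ns, 0, 2 * pi * p$bandwidth / fs))
      osc <- p$amplitude * sin(2 * pi * p$freq * (tidx - 1) / fs +
                                 stats::runif(1, 0, 2 * pi) + drift)
      sig[ch, ] <- sig[ch, ] + osc * env
    }
  }
  sig <- sig * gains
  events <- data.frame(onset = cues, code = 769L + labels)
  raw_recording(sig, fs, sprintf("EEG-%02d", seq_len(cfg$n_channels)),
                events, subject_id, session)
}

#' Generate a normalized synthetic epoch set
#'
#' Composition of [generate_recording()], [extract_epochs()] (cue-locked
#' `[1, 4)` s window) and [normalize_epochs()]; labels are balanced by
#' construction.
#'
#' @inheritParams generate_recording
#' @param normalize apply the default per-trial/channel z-score (TRUE).
#' @param window cue-relative window seconds.
#' @export
generate_epochset <- function(cfg, subject_id = "S01", session = "T",
                              normalize = TRUE, window = c(1, 4)) {
  rec <- generate_recording(cfg, subject_id, session)
  ep <- extract_epochs(rec, window = window)
  if (normalize) ep <- normalize_epochs(ep) else ep
}

#' Generate the full multi-subject synthetic study
#'
#' @param cfg a [synth_config()].
#' @param sessions which sessions to generate per subject.
#' @return named list (one entry per subject) of lists of [epoch_set]s keyed
#'   by session.
#' @export
generate_study <- function(cfg, sessions = c("T", "E")) {
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  out <- lapply(subjects, function(s) {
    es <- lapply(sessions, function(ss) generate_epochset(cfg, s, ss))
    names(es) <- sessions
    es
  })
  names(out) <- subjects
  out
}
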