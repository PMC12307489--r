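# Minimal GDF 1.25 reader and writer covering what BCI-IV-2A-style motor
# imagery recordings need: float32 or int16 samples, per-channel labels and
# physical ranges, and a mode-1 event table (onset + code). The byte layout
# follows the published GDF 1.x header map; round-trips are cross-checked
# against an independent GDF implementation in the test-suite.

write_int64le <- function(con, x) {
  # magnitudes in this package fit in 32 bits; two's-complement high word
  for (v in x)
    writeBin(c(as.integer(v), if (v < 0) -1L else 0L), con, size = 4L,
             endian = "little")
}

read_int64le <- function(con, n = 1L) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    lo <- if (w[1] < 0) w[1] + 2^32 else w[1]
    out[i] <- if (w[2] == -1L) w[1] else lo + w[2] * 2^32
  }
  out
}

pad_str <- function(s, width) {
  raw_s <- charToRaw(s)
  if (length(raw_s) > width) raw_s <- raw_s[seq_len(width)]
  c(raw_s, rep(as.raw(0x20), width - length(raw_s)))
}

#' Write a GDF 1.25 recording
#'
#' Stores a continuous multichannel signal (float32 samples, one 1-second
#' record per sampling-rate block) with channel labels and a mode-1 event
#' table. Used to build on-disk fixtures from the synthetic generator.
#'
#' @param rec a [raw_recording].
#' @param path output file.
#' @export
write_gdf <- function(rec, path) {
  sig <- rec$signal
  nchan <- nrow(sig)
  fs <- as.integer(rec$sampling_rate)
  ns <- ncol(sig)
  n_records <- ceiling(ns / fs)
  if (n_records * fs > ns) { # zero-pad the trailing partial record
    sig <- cbind(sig, matrix(0, nchan, n_records * fs - ns))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pad_str("GDF 1.25", 8L), con)
  writeBin(pad_str(paste0(rec$subject_id %||% "X", " X"), 80L), con)
  writeBin(pad_str(paste0("session ", rec$session %||% "T"), 80L), con)
  writeBin(pad_str("2026010100000000", 16L), con)
  write_int64le(con, 256 + 256 * nchan)  # header length
  writeBin(rep(as.raw(0), 24L), con)     # equipment / hospital / technician
  writeBin(rep(as.raw(0), 20L), con)     # reserved
  write_int64le(con, n_records)
  writeBin(c(1L, 1L), con, size = 4L, endian = "little") # record length 1 s
  writeBin(as.integer(nchan), con, size = 4L, endian = "little")
  for (i in seq_len(nchan)) writeBin(pad_str(rec$channel_labels[i], 16L), con)
  for (i in seq_len(nchan)) writeBin(pad_str("", 80L), con)
  for (i in seq_len(nchan)) writeBin(pad_str("uV", 8L), con)
  pmin_ <- rep(-5000, nchan); pmax_ <- rep(5000, nchan)
  writeBin(pmin_, con, size = 8L, endian = "little")
  writeBin(pmax_, con, size = 8L, endian = "little")
  write_int64le(con, pmin_)   # digital range = physical range (identity cal)
  write_int64le(con, pmax_)
  for (i in seq_len(nchan)) writeBin(pad_str("none", 80L), con)
  writeBin(rep(fs, nchan), con, size = 4L, endian = "little")  # samples/record
  writeBin(rep(16L, nchan), con, size = 4L, endian = "little") # float32
  writeBin(rep(as.raw(0), 32L * nchan), con)
  for (r in seq_len(n_records)) {
    block <- sig[, ((r - 1) * fs + 1):(r * fs), drop = FALSE]
    writeBin(as.numeric(t(block)), con, size = 4L, endian = "little")
  }
  # event table, mode 1: onsets are stored 1-based
  ev <- rec$events
  writeBin(as.raw(1L), con)
  fs_bytes <- as.raw(c(fs %% 256, (fs %/% 256) %% 256, fs %/% 65536))
  writeBin(fs_bytes, con)
  writeBin(as.integer(nrow(ev)), con, size = 4L, endian = "little")
  if (nrow(ev)) {
    writeBin(as.integer(ev$onset + 1L), con, size = 4L, endian = "little")
    for (cd in as.integer(ev$code))
      writeBin(as.raw(c(cd %% 256, cd %/% 256)), con)
  }
  invisible(path)
}

read_gdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- rawToChar(readBin(con, "raw", 8L))
  if (!startsWith(version, "GDF 1"))
    stop("unsupported or unreadable GDF file (version '", trimws(version), "')")
  patient <- trimws(rawToChar(readBin(con, "raw", 80L)))
  invisible(readBin(con, "raw", 80L + 16L)) # recording id + date
  header_nbytes <- read_int64le(con)
  invisible(readBin(con, "raw", 24L + 20L))
  n_records <- read_int64le(con)
  rl <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  nchan <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(nchan) || nchan < 1) stop("truncated GDF header")
  labels <- vapply(seq_len(nchan), function(i) {
    r <- readBin(con, "raw", 16L)
    trimws(rawToChar(r[r != as.raw(0)]))
  }, character(1))
  invisible(readBin(con, "raw", 80L * nchan))
  units <- vapply(seq_len(nchan), function(i) {
    r <- readBin(con, "raw", 8L)
    trimws(rawToChar(r[r != as.raw(0)]))
  }, character(1))
  pmin_ <- readBin(con, "numeric", nchan, size = 8L, endian = "little")
  pmax_ <- readBin(con, "numeric", nchan, size = 8L, endian = "little")
  dmin_ <- read_int64le(con, nchan)
  dmax_ <- read_int64le(con, nchan)
  invisible(readBin(con, "raw", 80L * nchan))
  n_samps <- readBin(con, "integer", nchan, size = 4L, endian = "little")
  dtypes <- readBin(con, "integer", nchan, size = 4L, endian = "little")
  invisible(readBin(con, "raw", 32L * nchan))
  if (length(unique(dtypes)) != 1L) stop("mixed GDF sample types not supported")
  fs <- max(n_samps) * rl[2] / rl[1]
  read_block <- function(n) {
    switch(as.character(dtypes[1]),
           "3" = readBin(con, "integer", n, size = 2L, endian = "little"),
           "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
           "17" = readBin(con, "numeric", n, size = 8L, endian = "little"),
           stop("unsupported GDF sample type ", dtypes[1]))
  }
  sig <- matrix(0, nchan, n_records * max(n_samps))
  for (r in seq_len(n_records)) {
    for (ch in seq_len(nchan)) {
      v <- read_block(n_samps[ch])
      if (length(v) < n_samps[ch]) stop("truncated GDF data section")
      sig[ch, ((r - 1) * n_samps[ch] + 1):(r * n_samps[ch])] <- v
    }
  }
  # calibration to physical units
  cal <- (pmax_ - pmin_) / (dmax_ - dmin_)
  off <- pmin_ - cal * dmin_
  sig <- sig * cal + off
  # event table
  events <- data.frame(onset = integer(0), code = integer(0))
  mode_raw <- readBin(con, "raw", 1L)
  if (length(mode_raw) == 1L && as.integer(mode_raw) %in% c(1L, 3L)) {
    invisible(readBin(con, "raw", 3L))
    n_ev <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n_ev) == 1L && !is.na(n_ev) && n_ev > 0) {
      pos <- readBin(con, "integer", n_ev, size = 4L, endian = "little") - 1L
      typ <- vapply(seq_len(n_ev), function(i) {
        b <- as.integer(readBin(con, "raw", 2L))
        b[1] + 256L * b[2]
      }, integer(1))
      events <- data.frame(onset = pos, code = typ)
    }
  }
  list(signal = sig, sampling_rate = fs, channel_labels = labels,
       units = units, events = events, patient = patient,
       header_nbytes = header_nbytes)
}
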