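# Minimal MAT v4 (Level 1.0) numeric-matrix reader/writer -- enough to carry
# the per-trial class-label vectors that accompany evaluation sessions
# (e.g. A01E.mat with its `classlabel` variable).

#' @noRd
write_mat_v4 <- function(vars, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(vars)) {
    m <- vars[[nm]]
    if (is.null(dim(m))) m <- matrix(as.numeric(m), ncol = 1L)
    storage.mode(m) <- "double"
    writeBin(0L, con, size = 4L, endian = "little")            # type MOPT=0000
    writeBin(nrow(m), con, size = 4L, endian = "little")
    writeBin(ncol(m), con, size = 4L, endian = "little")
    writeBin(0L, con, size = 4L, endian = "little")            # imagf
    writeBin(nchar(nm) + 1L, con, size = 4L, endian = "little")
    writeBin(c(charToRaw(nm), as.raw(0)), con)
    writeBin(as.numeric(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' @noRd
read_mat_v4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- file.info(path)$size
  out <- list()
  while (seek(con, where = NA) < sz) {
    hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
    if (length(hdr) < 5L) break
    type <- hdr[1]
    if (type %/% 1000 != 0 || type %% 10 > 1)
      stop("unsupported MAT v4 matrix type ", type)
    mrows <- hdr[2]; ncols <- hdr[3]; imagf <- hdr[4]; namlen <- hdr[5]
    nm_raw <- readBin(con, "raw", namlen)
    nm <- rawToChar(nm_raw[nm_raw != as.raw(0)])
    prec <- (type %/% 10) %% 100
    vals <- switch(as.character(prec),
                   "0" = readBin(con, "numeric", mrows * ncols, size = 8L,
                                 endian = "little"),
                   "1" = readBin(con, "numeric", mrows * ncols, size = 4L,
                                 endian = "little"),
                   "2" = readBin(con, "integer", mrows * ncols, size = 4L,
                                 endian = "little"),
                   "3" = readBin(con, "integer", mrows * ncols, size = 2L,
                                 endian = "little"),
                   stop("unsupported MAT v4 precision ", prec))
    if (imagf) invisible(readBin(con, "raw", mrows * ncols * 8L))
    out[[nm]] <- matrix(vals, mrows, ncols)
  }
  out
}
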