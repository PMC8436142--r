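# Minimal EDF (European Data Format) reader/writer for continuous signals.
# EDF stores 16-bit integers with per-signal linear scaling; one data record
# per second is written here.  Annotations (EDF+) are not handled.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' The signal is scaled to the full 16-bit digital range over its physical
#' min/max, so round-trips are exact up to one quantization step.  The last
#' data record is zero-padded if the recording is not a whole number of
#' seconds; the true sample count is recoverable from the header only to
#' record resolution, so prefer whole-second recordings.
#'
#' @param rec a [recording()] (or list of recordings sharing one fs).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  recs <- if (inherits(rec, "tfs_recording")) list(rec) else rec
  fs <- recs[[1]]$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  ns <- length(recs)
  n <- max(vapply(recs, function(r) length(r$samples), 0))
  ndr <- ceiling(n / fs)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
                edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
                edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
                edf_pad(ndr, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmins <- pmaxs <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- range(recs[[i]]$samples, 0)
    span <- diff(rng)
    if (span == 0) span <- 1
    pmins[i] <- rng[1] - 0.001 * span
    pmaxs[i] <- rng[2] + 0.001 * span
  }
  fields <- list(
    vapply(recs, function(r) r$channel, ""), rep("", ns),
    rep("uV", ns), formatC(pmins, format = "g", digits = 7),
    formatC(pmaxs, format = "g", digits = 7),
    rep("-32768", ns), rep("32767", ns), rep("", ns), rep(fs, ns), rep("", ns))
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  for (k in seq_along(fields))
    writeChar(paste(edf_pad(fields[[k]], widths[k]), collapse = ""), con, eos = NULL)
  dig <- matrix(0L, nrow = ndr * fs, ncol = ns)
  for (i in seq_len(ns)) {
    x <- c(recs[[i]]$samples, numeric(ndr * fs - length(recs[[i]]$samples)))
    g <- (x - pmins[i]) / (pmaxs[i] - pmins[i]) * 65535 - 32768
    dig[, i] <- as.integer(round(pmin(pmax(g, -32768), 32767)))
  }
  for (r in seq_len(ndr))
    for (i in seq_len(ns))
      writeBin(dig[((r - 1) * fs + 1):(r * fs), i], con, size = 2, endian = "little")
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path EDF file path.
#' @param channel channel label; defaults to the first signal.
#' @return a [recording()] at the channel's native sampling rate, in the
#'   physical units declared by the header (µV for files written by
#'   [write_edf()]).
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("not an EDF file (version field '", version, "')")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes (recomputed below)
  rd(44)
  ndr <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  per_sig <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- per_sig(16); per_sig(80); per_sig(8)
  pmin <- as.numeric(per_sig(8)); pmax <- as.numeric(per_sig(8))
  dmin <- as.numeric(per_sig(8)); dmax <- as.numeric(per_sig(8))
  per_sig(80); spr <- as.integer(per_sig(8)); per_sig(32)
  if (is.null(channel)) {
    ci <- 1L
  } else {
    ci <- match(channel, labels)
    if (is.na(ci)) stop("channel '", channel, "' not found; available: ",
                        paste(labels, collapse = ", "))
  }
  out <- integer(ndr * spr[ci])
  off <- cumsum(c(0, spr))
  for (r in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little", signed = TRUE)
      if (i == ci) out[((r - 1) * spr[ci] + 1):(r * spr[ci])] <- v
    }
  }
  phys <- pmin[ci] + (out - dmin[ci]) * (pmax[ci] - pmin[ci]) / (dmax[ci] - dmin[ci])
  recording(phys, fs = spr[ci] / dur, channel = labels[ci])
}
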