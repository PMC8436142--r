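#' Single-channel EEG recording
#'
#' A light container for one channel of EEG: a numeric sample vector in
#' microvolts, its sampling rate, a channel label and a time origin.  All
#' event times in the package are seconds from `t0`, with sample `i`
#' (1-based) covering the half-open interval `[(i-1)/fs, i/fs)`.
#'
#' @param samples numeric vector of samples (µV).
#' @param fs sampling rate (Hz), > 0.
#' @param channel channel label.
#' @param t0 time origin in seconds (default 0).
#' @return an object of class `tfs_recording` with fields `samples`, `fs`,
#'   `channel`, `t0`.
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 13 * seq(0, 10, by = 0.01)), fs = 100)
#' duration_s(rec)
recording <- function(samples, fs, channel = "EEG", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) stop("recording needs at least one sample")
  if (!all(is.finite(samples))) stop("recording samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  structure(list(samples = samples, fs = fs,
                 channel = as.character(channel), t0 = t0),
            class = "tfs_recording")
}

#' @export
print.tfs_recording <- function(x, ...) {
  cat(sprintf("<tfs_recording> channel=%s fs=%g Hz n=%d (%.1f s)\n",
              x$channel, x$fs, length(x$samples), duration_s(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @export
duration_s <- function(rec) length(rec$samples) / rec$fs

#' Canonical sleep stage vocabulary
#' @keywords internal
STAGES <- c("W", "N1", "N2", "N3", "REM", "UNKNOWN")

#' Per-epoch sleep stage sequence
#'
#' @param stages character vector of stage codes, one per epoch, from
#'   `W, N1, N2, N3, REM, UNKNOWN`.
#' @param epoch_s epoch length in seconds (default 30, the clinical standard).
#' @return an object of class `tfs_hypnogram`.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  if (epoch_s <= 0) stop("epoch_s must be positive")
  bad <- !(stages %in% STAGES)
  if (any(bad)) stop("unrecognized stage codes: ",
                     paste(unique(stages[bad]), collapse = ", "),
                     " (use read_hypnogram() for alias mapping)")
  structure(list(stages = stages, epoch_s = epoch_s), class = "tfs_hypnogram")
}

#' @export
print.tfs_hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat(sprintf("<tfs_hypnogram> %d epochs x %g s: %s\n", length(x$stages),
              x$epoch_s, paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Expand a hypnogram to one stage label per sample
#'
#' The last epoch may be partial; samples beyond the hypnogram's coverage
#' are labelled UNKNOWN with a warning.
#'
#' @param hyp a [hypnogram()].
#' @param n_samples number of samples to cover.
#' @param fs sampling rate (Hz).
#' @export
stage_per_sample <- function(hyp, n_samples, fs) {
  epoch_n <- hyp$epoch_s * fs
  idx <- floor((seq_len(n_samples) - 1) / epoch_n) + 1
  over <- idx > length(hyp$stages)
  if (any(over)) {
    if (mean(over) > 0.01)
      warning("hypnogram covers only ",
              round(length(hyp$stages) * hyp$epoch_s), " s of ",
              round(n_samples / fs), " s; tail labelled UNKNOWN")
    idx[over] <- NA
  }
  out <- hyp$stages[idx]
  out[is.na(out)] <- "UNKNOWN"
  out
}

#' Total minutes spent in a stage
#' @param hyp a [hypnogram()].
#' @param stage stage code (default "N2").
#' @export
stage_minutes <- function(hyp, stage = "N2") {
  sum(hyp$stages == stage) * hyp$epoch_s / 60
}

#' Build a validated event table
#'
#' The common currency for detected or scored events: a data frame with
#' half-open intervals `[start_s, end_s)` in seconds from recording start,
#' a `method` tag and `subject`/`night` identifiers, plus optional linked
#' time-frequency peak property columns (`prominence_db`, `duration_s`,
#' `central_freq_hz`, `bandwidth_hz`).
#'
#' @param start_s,end_s event bounds (s); `start_s < end_s`, `start_s >= 0`.
#' @param method method tag.
#' @param subject,night identifiers.
#' @param ... further equal-length columns (e.g. peak properties).
#' @return a `data.frame` with class `tfs_events`.
#' @export
event_table <- function(start_s = numeric(), end_s = numeric(),
                        method = "unknown", subject = "s1", night = 1L, ...) {
  n <- length(start_s)
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   method = rep_len(method, n), subject = rep_len(subject, n),
                   night = rep_len(night, n), ..., stringsAsFactors = FALSE)
  validate_event_table(df)
}

#' @rdname event_table
#' @param df a data frame with at least `start_s`, `end_s`, `method`,
#'   `subject`, `night`.
#' @export
validate_event_table <- function(df) {
  req <- c("start_s", "end_s", "method", "subject", "night")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("event table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    if (anyNA(df[req])) stop("NA in required event table columns")
    bad <- which(!(df$start_s < df$end_s))
    if (length(bad)) stop("start_s >= end_s in row(s) ", paste(bad, collapse = ", "))
    if (any(df$start_s < 0)) stop("negative start_s")
  }
  class(df) <- unique(c("tfs_events", class(df)))
  df
}
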