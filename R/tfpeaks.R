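#' Frequency step: per-column sigma-range peak prominence
#'
#' For every spectrogram time column, the power spectrum is converted to dB
#' and searched for interior local maxima over the full frequency grid.
#' The topographic prominence of each maximum (height above the higher of
#' its two flanking minima, searched across the whole spectrum) is
#' computed, and the largest-prominence peak whose apex lies within
#' `f_range` is recorded: its prominence, central frequency and spectral
#' width at half prominence.  Computing the bases over the full spectrum
#' (rather than clipping them at the band edges) keeps the trace stable
#' when the sigma lobe fills most of the search band.  Columns without a
#' local maximum in `f_range` get prominence 0.
#'
#' @param spec a `tfs_spectrogram`.
#' @param f_range search band (Hz), default 9-17: the 10-16 Hz sigma range
#'   widened by 1 Hz on each side to accommodate the estimator's main-lobe
#'   bandwidth; final event filtering to 10-16 Hz happens downstream.
#' @return object of class `tfs_prom_trace`: list with `times`, `value`
#'   (prominence, dB), `freq_at` (Hz), `band_at` (half-prominence spectral
#'   width, Hz), `step_s`, plus the band frequency grid.
#' @export
frequency_step <- function(spec, f_range = c(9, 17)) {
  stopifnot(length(f_range) == 2, f_range[1] < f_range[2])
  if (f_range[1] < min(spec$freqs) || f_range[2] > max(spec$freqs))
    stop("f_range outside the spectrogram frequency grid")
  rows <- which(spec$freqs >= f_range[1] & spec$freqs <= f_range[2])
  if (length(rows) < 3) stop("f_range spans fewer than 3 frequency bins")
  db <- 10 * log10(pmax(spec$power, 1e-300))
  res <- col_prominence_cpp(db, min(rows), max(rows))
  df <- spec$freqs[2] - spec$freqs[1]
  freq_at <- spec$freqs[1] + (res$row_at - 1) * df
  structure(list(times = spec$times, value = res$value, freq_at = freq_at,
                 band_at = res$width * df, step_s = spec$params$step_s),
            class = "tfs_prom_trace")
}

#' Time step: temporal peaks of the prominence trace
#'
#' Finds local maxima of the prominence trace over time.  Each maximum
#' becomes one time-frequency peak: apex at the maximum, temporal bounds at
#' the half-prominence crossings of the temporal peak (linear
#' interpolation on the time grid), prominence equal to the trace value at
#' the apex, and central frequency / bandwidth taken from the frequency
#' step at the apex.  Output is ordered by apex time.
#'
#' @param trace a `tfs_prom_trace` from [frequency_step()].
#' @return data frame of class `tfs_peaks` with columns `t_peak`, `t_lo`,
#'   `t_hi`, `prominence_db`, `duration_s`, `central_freq`, `f_lo`, `f_hi`,
#'   `bandwidth_hz`.
#' @export
time_step <- function(trace) {
  empty <- data.frame(t_peak = numeric(), t_lo = numeric(), t_hi = numeric(),
                      prominence_db = numeric(), duration_s = numeric(),
                      central_freq = numeric(), f_lo = numeric(),
                      f_hi = numeric(), bandwidth_hz = numeric())
  if (length(trace$value) < 3) return(structure(empty, class = c("tfs_peaks", "data.frame")))
  pk <- peaks_1d_cpp(trace$value)
  if (!nrow(pk)) return(structure(empty, class = c("tfs_peaks", "data.frame")))
  at <- function(pos) {  # fractional index -> time on the uniform grid
    trace$times[1] + (pos - 1) * trace$step_s
  }
  cf <- trace$freq_at[pk$idx]
  bw <- trace$band_at[pk$idx]
  out <- data.frame(t_peak = trace$times[pk$idx], t_lo = at(pk$lo),
                    t_hi = at(pk$hi), prominence_db = trace$value[pk$idx],
                    duration_s = (pk$hi - pk$lo) * trace$step_s,
                    central_freq = cf, f_lo = cf - bw / 2, f_hi = cf + bw / 2,
                    bandwidth_hz = bw)
  out <- out[order(out$t_peak, out$central_freq), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tfs_peaks", "data.frame"))
}

#' Most prominent peak within an event interval
#'
#' Among peaks whose apex time falls in `[start_s, end_s)`, returns the one
#' with maximal prominence (ties: earliest apex, then lowest frequency), or
#' `NULL` if none.
#'
#' @param start_s,end_s event interval bounds (s).
#' @param peaks a `tfs_peaks` data frame.
#' @export
most_prominent_in_interval <- function(start_s, end_s, peaks) {
  inside <- peaks$t_peak >= start_s & peaks$t_peak < end_s
  if (!any(inside)) return(NULL)
  cand <- peaks[inside, , drop = FALSE]
  cand <- cand[order(-cand$prominence_db, cand$t_peak, cand$central_freq), ,
               drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Assign peak properties to a table of events
#'
#' For each event the most prominent peak during the event is found and its
#' properties (`prominence_db`, `duration_s`, `central_freq_hz`,
#' `bandwidth_hz`) are attached; events containing no peak get NA.
#'
#' @param events an event table.
#' @param peaks a `tfs_peaks` data frame.
#' @export
assign_peak_properties <- function(events, peaks) {
  n <- nrow(events)
  events$prominence_db <- events$duration_s <- events$central_freq_hz <-
    events$bandwidth_hz <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    p <- most_prominent_in_interval(events$start_s[i], events$end_s[i], peaks)
    if (!is.null(p)) {
      events$prominence_db[i] <- p$prominence_db
      events$duration_s[i] <- p$duration_s
      events$central_freq_hz[i] <- p$central_freq
      events$bandwidth_hz[i] <- p$bandwidth_hz
    }
  }
  events
}
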