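#' TF-sigma detection parameters
#'
#' Candidate peaks shorter than `min_duration_s` (0.3 s, the consensus
#' lower bound on spindle duration) or narrower than `min_bandwidth_hz`
#' (2 Hz, half the 4 Hz spectral resolution of the default multitaper
#' configuration, below which peaks are not resolvable) are excluded before
#' clustering; detected events are finally restricted to
#' `[freq_lo, freq_hi]` by central frequency.
#'
#' @param min_duration_s minimum candidate duration (s).
#' @param min_bandwidth_hz minimum candidate bandwidth (Hz).
#' @param freq_lo,freq_hi reporting band (Hz).
#' @export
tfsigma_params <- function(min_duration_s = 0.3, min_bandwidth_hz = 2,
                           freq_lo = 10, freq_hi = 16) {
  stopifnot(min_duration_s > 0, freq_lo < freq_hi)
  structure(list(min_duration_s = min_duration_s,
                 min_bandwidth_hz = min_bandwidth_hz,
                 freq_lo = freq_lo, freq_hi = freq_hi, k = 2L),
            class = "tfs_tfsigma_params")
}

#' Filter candidate peaks by duration and bandwidth
#'
#' @param peaks a `tfs_peaks` data frame.
#' @param params a [tfsigma_params()].
#' @return the retained rows, order preserved.
#' @export
filter_candidates <- function(peaks, params = tfsigma_params()) {
  keep <- peaks$duration_s >= params$min_duration_s &
    peaks$bandwidth_hz >= params$min_bandwidth_hz
  peaks[keep, , drop = FALSE]
}

#' Exact two-class k-means in one dimension
#'
#' In 1-D the optimal two-class k-means partition is a contiguous split of
#' the sorted values, so the within-class sum of squares can be minimized
#' exactly by enumerating all splits with prefix sums.  This removes any
#' dependence on random initialization: the result is deterministic and
#' globally optimal.  Ties in the objective break towards the smaller
#' event class.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return list with `threshold` (midpoint of the class means), `labels`
#'   (per input value, "event" for the higher-mean class else "noise"),
#'   `means` (named noise/event class means), `wcss`.
#' @export
kmeans_two_class <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct values to separate two classes")
  o <- order(x)
  s <- x[o]
  n <- length(s)
  cs <- cumsum(s); css <- cumsum(s^2)
  j <- seq_len(n - 1)                       # lower class = s[1..j]
  wcss_lo <- css[j] - cs[j]^2 / j
  wcss_hi <- (css[n] - css[j]) - (cs[n] - cs[j])^2 / (n - j)
  tot <- wcss_lo + wcss_hi
  jbest <- j[which.min(tot)]
  m_lo <- cs[jbest] / jbest
  m_hi <- (cs[n] - cs[jbest]) / (n - jbest)
  labels <- character(n)
  labels[o[seq_len(jbest)]] <- "noise"
  labels[o[(jbest + 1):n]] <- "event"
  list(threshold = (m_lo + m_hi) / 2, labels = labels,
       means = c(noise = m_lo, event = m_hi), wcss = tot[which.min(tot)])
}

# Zero the prominence trace wherever the analysis window overlaps an
# artifact-masked sample, so no peak apex can fall on contaminated data.
blank_masked_columns <- function(trace, mask, window_s) {
  if (is.null(mask) || !any(mask$mask)) return(trace)
  bad_t <- (which(mask$mask) - 0.5) / mask$fs
  half <- window_s / 2
  # column j's window spans [times[j] - half, times[j] + half]
  lo <- trace$times - half
  hi <- trace$times + half
  bt <- sort(bad_t)
  i1 <- findInterval(lo, bt)        # bad samples strictly before lo
  i2 <- findInterval(hi, bt)        # bad samples at or before hi
  hit <- i2 > i1
  trace$value[hit] <- 0
  trace
}

#' Unsupervised detection of sigma-range time-frequency peaks
#'
#' Full pipeline: multitaper spectrogram, two-step prominence peak
#' extraction over the artifact-free record, duration/bandwidth candidate
#' filtering, natural-log transform of prominence (prominences are
#' approximately log-normal), exact two-class k-means separation of events
#' from noise peaks, and a final restriction of events to the 10-16 Hz
#' band by central frequency.  The whole chain is deterministic.
#'
#' @param rec a [recording()].
#' @param hyp optional [hypnogram()] (carried through to the output table;
#'   stage-based event selection is a separate step, see [select_events()]).
#' @param mask optional `tfs_artifact_mask`; spectrogram columns whose
#'   window overlaps a flagged sample are excluded from peak extraction.
#' @param params a [tfsigma_params()].
#' @param spec_params a [spectrogram_params()].
#' @param subject,night identifiers stamped on the output.
#' @return event table (class `tfs_events`) with one row per detected TF
#'   sigma peak (`[t_lo, t_hi)` as `start_s`/`end_s`) and property columns
#'   `prominence_db`, `duration_s`, `central_freq_hz`, `bandwidth_hz`.
#'   Attribute `"cluster"` holds the [kmeans_two_class()] result plus the
#'   candidate count; attribute `"trace"` the prominence trace.
#' @export
detect_tfsigma <- function(rec, hyp = NULL, mask = NULL,
                           params = tfsigma_params(),
                           spec_params = spectrogram_params(),
                           subject = "s1", night = 1L) {
  spec <- compute_spectrogram(rec, spec_params)
  band <- c(params$freq_lo - 1, params$freq_hi + 1)
  trace <- frequency_step(spec, band)
  trace <- blank_masked_columns(trace, mask, spec_params$window_s)
  peaks <- time_step(trace)
  cand <- filter_candidates(peaks, params)
  if (nrow(cand) < 2)
    stop("too few candidate peaks to cluster (", nrow(cand),
         "); provide a longer recording")
  cl <- kmeans_two_class(log(cand$prominence_db))
  cl$n_candidates <- nrow(cand)
  ev <- cand[cl$labels == "event", , drop = FALSE]
  ev <- ev[ev$central_freq >= params$freq_lo & ev$central_freq <= params$freq_hi, ,
           drop = FALSE]
  out <- event_table(start_s = ev$t_lo, end_s = ev$t_hi, method = "tfsigma",
                     subject = subject, night = night,
                     prominence_db = ev$prominence_db,
                     duration_s = ev$duration_s,
                     central_freq_hz = ev$central_freq,
                     bandwidth_hz = ev$bandwidth_hz)
  attr(out, "cluster") <- cl
  attr(out, "trace") <- trace
  out
}
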