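#' Wavelet spindle detector parameters
#'
#' The detector convolves the trace with a bank of complex Morlet wavelets
#' whose center frequencies span the sigma band, computes the square of the
#' real part of the squared wavelet coefficient at each sample, averages
#' across scales and smooths with a `smooth_ms` moving average.  The
#' detection threshold is `threshold_scalar` times the mean of this
#' statistic over artifact-free N2 sleep; supra-threshold runs of at least
#' `min_dur_s` become spindle events, runs longer than `max_dur_s` are
#' truncated, and an event starting less than `min_sep_s` after the
#' previous onset is discarded.
#'
#' The precise wavelet parameterization of the original (MATLAB)
#' implementation is not published; here the bank uses integer center
#' frequencies `f_lo:f_hi` with a fixed `n_cycles` per wavelet, which
#' reproduces the stated 10-16 Hz scale coverage.
#'
#' @param f_lo,f_hi passband of wavelet center frequencies (Hz).
#' @param smooth_ms moving-average window (ms).
#' @param threshold_scalar multiplier of the N2 mean statistic.
#' @param min_dur_s,max_dur_s event duration limits (s).
#' @param min_sep_s minimal separation between consecutive onsets (s).
#' @param n_cycles wavelet width in cycles.
#' @param center_freqs optional explicit center-frequency vector (Hz).
#' @export
wavelet_params <- function(f_lo = 10, f_hi = 16, smooth_ms = 100,
                           threshold_scalar = 4.5, min_dur_s = 0.3,
                           max_dur_s = 3, min_sep_s = 1, n_cycles = 7,
                           center_freqs = NULL) {
  stopifnot(f_lo < f_hi, threshold_scalar > 0, min_dur_s > 0,
            min_dur_s < max_dur_s)
  if (is.null(center_freqs)) center_freqs <- seq(f_lo, f_hi, by = 1)
  structure(list(f_lo = f_lo, f_hi = f_hi, smooth_ms = smooth_ms,
                 threshold_scalar = threshold_scalar, min_dur_s = min_dur_s,
                 max_dur_s = max_dur_s, min_sep_s = min_sep_s,
                 n_cycles = n_cycles, center_freqs = center_freqs),
            class = "tfs_wavelet_params")
}

# FFT-based convolution with a bank of complex Morlet wavelets; returns the
# scale-averaged statistic (Re(W^2))^2 per sample.
morlet_statistic <- function(x, fs, params) {
  n <- length(x)
  kernels <- lapply(params$center_freqs, function(f) {
    sigma <- params$n_cycles / (2 * pi * f)
    half <- ceiling(4 * sigma * fs)
    t <- (-half:half) / fs
    w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma^2))
    w / sum(Mod(w))                       # L1 normalization
  })
  lk <- max(vapply(kernels, length, 0L))
  nfft <- 2^ceiling(log2(n + lk - 1))
  X <- stats::fft(c(x, numeric(nfft - n)))
  acc <- numeric(n)
  for (w in kernels) {
    K <- stats::fft(c(w, complex(nfft - length(w))))
    conv <- stats::fft(X * K, inverse = TRUE) / nfft
    center <- (length(w) - 1) / 2
    W <- conv[(center + 1):(center + n)]
    acc <- acc + Re(W^2)^2
  }
  acc / length(kernels)
}

#' Smoothed wavelet magnitude statistic
#'
#' @param rec a [recording()].
#' @param params a [wavelet_params()].
#' @return list of class `tfs_magnitude_trace`: `times` (s, per sample),
#'   `value` (statistic, arbitrary units >= 0), `fs`.
#' @export
magnitude_trace <- function(rec, params = wavelet_params()) {
  if (params$f_hi >= rec$fs / 2)
    stop("wavelet passband upper edge must be below fs/2")
  stat <- morlet_statistic(rec$samples, rec$fs, params)
  k <- max(1L, round(params$smooth_ms / 1000 * rec$fs))
  structure(list(times = rec$t0 + (seq_along(stat) - 1) / rec$fs,
                 value = moving_average(stat, k), fs = rec$fs),
            class = "tfs_magnitude_trace")
}

# Extract events from a magnitude trace given an absolute threshold.
threshold_events <- function(value, fs, threshold, params) {
  r <- rle(value > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths        # 0-based
  keep <- r$values & (r$lengths / fs >= params$min_dur_s)
  if (!any(keep)) return(data.frame(start_s = numeric(), end_s = numeric()))
  st <- starts[keep] / fs
  en <- ends[keep] / fs
  en <- pmin(en, st + params$max_dur_s)         # truncate long runs
  sel <- logical(length(st))
  last_onset <- -Inf
  for (i in seq_along(st)) {
    if (st[i] - last_onset >= params$min_sep_s) {
      sel[i] <- TRUE
      last_onset <- st[i]
    }
  }
  data.frame(start_s = st[sel], end_s = en[sel])
}

#' Wavelet-threshold spindle detection
#'
#' @param rec a [recording()].
#' @param hyp a [hypnogram()] with at least one N2 epoch (the threshold is
#'   anchored to the mean statistic during N2).
#' @param mask optional `tfs_artifact_mask`; masked samples are excluded
#'   from the threshold mean.
#' @param params a [wavelet_params()].
#' @param subject,night identifiers stamped on the output.
#' @return event table with method `"spindle"`.  Attributes `"threshold"`
#'   and `"n2_mean"` record the absolute threshold and the N2 mean
#'   statistic.
#' @export
detect_spindles <- function(rec, hyp, mask = NULL, params = wavelet_params(),
                            subject = "s1", night = 1L) {
  trace <- magnitude_trace(rec, params)
  ev <- spindles_from_trace(trace, hyp, mask, params, subject, night)
  ev
}

# Shared core so threshold optimization can reuse one trace.
spindles_from_trace <- function(trace, hyp, mask, params, subject = "s1",
                                night = 1L) {
  stage <- stage_per_sample(hyp, length(trace$value), trace$fs)
  ok <- stage == "N2"
  if (!any(ok)) stop("hypnogram contains no N2 epochs")
  if (!is.null(mask)) ok <- ok & !mask$mask
  n2_mean <- mean(trace$value[ok])
  thr <- params$threshold_scalar * n2_mean
  ev <- threshold_events(trace$value, trace$fs, thr, params)
  out <- event_table(start_s = ev$start_s, end_s = ev$end_s,
                     method = "spindle", subject = subject, night = night)
  attr(out, "threshold") <- thr
  attr(out, "n2_mean") <- n2_mean
  out
}

#' F1-optimization of the detection threshold
#'
#' Runs the detector over a grid of threshold scalars and scores each
#' result against a reference event table with [match_events()]; returns
#' the scalar maximizing F1 (ties resolved towards the largest scalar,
#' i.e. the most conservative detector) together with the full F1 curve.
#'
#' @param rec,hyp,mask,params as in [detect_spindles()].
#' @param reference nonempty reference event table.
#' @param grid threshold scalars to scan (default 0.01 to 4.5 by 0.01).
#' @param select_fn optional function applied to each candidate event table
#'   before scoring (e.g. stage-based event selection).
#' @return list with `best_scalar`, `best_f1`, and `curve` (data frame
#'   scalar/precision/recall/f1).
#' @export
optimize_threshold <- function(rec, hyp, mask = NULL, reference,
                               grid = seq(0.01, 4.5, by = 0.01),
                               params = wavelet_params(), select_fn = NULL) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("reference event table must be nonempty")
  trace <- magnitude_trace(rec, params)
  f1s <- prec <- rec_ <- numeric(length(grid))
  for (i in seq_along(grid)) {
    p <- params
    p$threshold_scalar <- grid[i]
    ev <- spindles_from_trace(trace, hyp, mask, p)
    if (!is.null(select_fn)) ev <- select_fn(ev)
    cs <- match_events(reference, ev, fs = rec$fs)
    f1s[i] <- cs$f1
    prec[i] <- cs$precision
    rec_[i] <- cs$recall
  }
  best <- max(which(f1s == max(f1s)))      # ties -> largest scalar
  list(best_scalar = grid[best], best_f1 = f1s[best],
       curve = data.frame(scalar = grid, precision = prec, recall = rec_,
                          f1 = f1s))
}
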