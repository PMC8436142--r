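#' Artifact detection parameters
#'
#' Two high-pass passes are run over the raw trace: one above `hf_cutoff`
#' (high-frequency noise) and one above `bb_cutoff` (broadband noise).  Each
#' pass takes the analytic-signal amplitude, log-transforms, smooths with a
#' `smooth_s` running average, removes slow drifts with a least-squares
#' cubic spline (`n_knots` interior knots), and iteratively flags samples
#' with |z| above `z_thresh` SDs, recomputing mean/SD over unmasked samples
#' until convergence.
#'
#' @param hf_cutoff high-frequency pass cutoff (Hz).
#' @param bb_cutoff broadband pass cutoff (Hz).
#' @param filter_order IIR (Butterworth) high-pass order.
#' @param smooth_s running-average window (s).
#' @param n_knots spline detrend interior knot count.
#' @param z_thresh z-score threshold (SD units).
#' @param max_iter iteration cap.
#' @export
artifact_params <- function(hf_cutoff = 35, bb_cutoff = 2, filter_order = 8,
                            smooth_s = 2, n_knots = 300, z_thresh = 4,
                            max_iter = 50) {
  stopifnot(z_thresh > 0, max_iter >= 1)
  structure(list(hf_cutoff = hf_cutoff, bb_cutoff = bb_cutoff,
                 filter_order = filter_order, smooth_s = smooth_s,
                 n_knots = n_knots, z_thresh = z_thresh, max_iter = max_iter),
            class = "tfs_artifact_params")
}

# Least-squares cubic B-spline detrend with uniformly spaced interior knots.
# The fit uses a decimated subgrid for speed; the curve is evaluated at all
# samples in chunks.
spline_trend <- function(y, n_knots) {
  n <- length(y)
  x <- seq_len(n)
  interior <- seq(1, n, length.out = n_knots + 2)[-c(1, n_knots + 2)]
  knots <- c(rep(1, 4), interior, rep(n, 4))
  m_target <- min(n, max(2000L, 30L * (n_knots + 4L)))
  ds <- max(1L, n %/% m_target)
  xi <- unique(c(seq(1, n, by = ds), n))
  B <- splines::splineDesign(knots, xi, ord = 4)
  coef <- qr.coef(qr(B), y[xi])
  coef[is.na(coef)] <- 0
  out <- numeric(n)
  for (lo in seq(1, n, by = 50000L)) {
    hi <- min(lo + 49999L, n)
    out[lo:hi] <- drop(splines::splineDesign(knots, x[lo:hi], ord = 4) %*% coef)
  }
  out
}

# One high-pass z-score pass; returns a logical mask
artifact_pass <- function(samples, fs, cutoff, params) {
  sos <- butter_sos(params$filter_order, cutoff, fs, "high")
  y <- sosfiltfilt(sos, samples)
  amp <- hilbert_amplitude(y)
  la <- log(amp + .Machine$double.eps)
  sm <- moving_average(la, round(params$smooth_s * fs))
  d <- sm - spline_trend(sm, params$n_knots)
  mask <- rep(FALSE, length(d))
  for (it in seq_len(params$max_iter)) {
    mu <- mean(d[!mask]); sd_ <- stats::sd(d[!mask])
    if (!is.finite(sd_) || sd_ == 0) break
    new <- !mask & abs(d - mu) > params$z_thresh * sd_
    if (!any(new)) break
    mask <- mask | new
  }
  mask
}

#' Iterative z-score artifact detection
#'
#' Runs the high-frequency and broadband passes described in
#' [artifact_params()] and returns the union of the two masks.  If the
#' sampling rate cannot support the high-frequency cutoff (fs/2 <=
#' `hf_cutoff`) that pass is skipped with a warning.
#'
#' @param rec a [recording()].
#' @param params an [artifact_params()].
#' @return object of class `tfs_artifact_mask`: list with `mask` (logical
#'   per sample, TRUE = artifact) and `fs`.
#' @export
detect_artifacts <- function(rec, params = artifact_params()) {
  if (!all(is.finite(rec$samples))) stop("non-finite samples in recording")
  fs <- rec$fs
  masks <- list()
  if (fs / 2 > params$hf_cutoff) {
    masks$hf <- artifact_pass(rec$samples, fs, params$hf_cutoff, params)
  } else {
    warning("fs/2 <= hf_cutoff (", params$hf_cutoff,
            " Hz): high-frequency pass skipped")
  }
  masks$bb <- artifact_pass(rec$samples, fs, params$bb_cutoff, params)
  mask <- Reduce(`|`, masks)
  structure(list(mask = mask, fs = fs), class = "tfs_artifact_mask")
}

#' An all-clean mask for a recording
#' @param rec a [recording()].
#' @export
empty_mask <- function(rec) {
  structure(list(mask = rep(FALSE, length(rec$samples)), fs = rec$fs),
            class = "tfs_artifact_mask")
}

#' Convert a per-sample mask to artifact intervals
#'
#' Maximal runs of flagged samples become half-open `[start_s, end_s)`
#' intervals on the recording's sample grid.
#'
#' @param mask a `tfs_artifact_mask`.
#' @return data frame with columns `start_s`, `end_s`.
#' @export
mask_to_intervals <- function(mask) {
  r <- rle(mask$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start_s = starts[keep] / mask$fs, end_s = ends[keep] / mask$fs)
}

#' Build a per-sample mask from artifact intervals
#' @param intervals data frame with `start_s`, `end_s`.
#' @param n_samples,fs target grid.
#' @export
intervals_to_mask <- function(intervals, n_samples, fs) {
  m <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(intervals))) {
    lo <- max(1L, floor(intervals$start_s[i] * fs) + 1L)
    hi <- min(n_samples, ceiling(intervals$end_s[i] * fs))
    if (lo <= hi) m[lo:hi] <- TRUE
  }
  structure(list(mask = m, fs = fs), class = "tfs_artifact_mask")
}
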