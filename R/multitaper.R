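#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` for time-half-bandwidth
#' product `tw` via the symmetric tridiagonal eigenproblem, normalized to
#' unit norm.  Polarity follows the usual convention (each taper's mean,
#' or for odd orders its leading slope, is positive).
#'
#' @param n taper length in samples.
#' @param tw time-half-bandwidth product.
#' @param k number of tapers (at most `2*tw - 1` for well-concentrated ones).
#' @return `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, tw, k) {
  stopifnot(n >= 2, k >= 1, k <= n)
  w <- tw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(d)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- e
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- e
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- if (j %% 2 == 1) sum(v[, j]) else sum(v[, j] * i)  # even/odd order
    if (s < 0) v[, j] <- -v[, j]
  }
  v
}

#' Multitaper spectrogram parameters
#'
#' Defaults follow the standard configuration for sleep EEG sigma-band
#' analysis: 1 s windows stepped by 0.05 s, time-half-bandwidth 2 with 3
#' Slepian tapers (spectral resolution 2*tw/window = 4 Hz), at least 1024
#' DFT points, and constant (mean) detrending within each window.
#'
#' @param window_s window length (s).
#' @param step_s window step (s).
#' @param tw time-half-bandwidth product.
#' @param n_tapers number of Slepian tapers; must be <= 2*tw - 1.
#' @param min_nfft minimum DFT length (zero-padded).
#' @param detrend "constant" or "off".
#' @export
spectrogram_params <- function(window_s = 1, step_s = 0.05, tw = 2,
                               n_tapers = 3, min_nfft = 1024,
                               detrend = c("constant", "off")) {
  detrend <- match.arg(detrend)
  if (n_tapers > 2 * tw - 1)
    stop("n_tapers must be <= 2*tw - 1 for well-concentrated tapers")
  if (step_s > window_s) stop("step_s must not exceed window_s")
  structure(list(window_s = window_s, step_s = step_s, tw = tw,
                 n_tapers = n_tapers, min_nfft = min_nfft, detrend = detrend),
            class = "tfs_spectrogram_params")
}

#' Spectral resolution of a parameter set (Hz)
#' @param params a [spectrogram_params()].
#' @export
spectral_resolution <- function(params) 2 * params$tw / params$window_s

#' Compute a multitaper spectrogram
#'
#' Windows are placed at offsets `k * step_s` from the recording start
#' (final partial window dropped) and timestamped at their centers.  Within
#' each window the mean is subtracted (constant detrend), each Slepian
#' taper is applied, and the taper periodograms are averaged and scaled to
#' one-sided power spectral density (µV²/Hz): division by `fs`, factor 2 on
#' non-DC/non-Nyquist bins.
#'
#' @param rec a [recording()].
#' @param params a [spectrogram_params()].
#' @param chunk windows per FFT batch (memory/time trade-off).
#' @return object of class `tfs_spectrogram` with fields `times` (s, window
#'   centers), `freqs` (Hz), `power` (frequency x time matrix, linear PSD),
#'   `params`, `fs`.
#' @export
compute_spectrogram <- function(rec, params = spectrogram_params(),
                                chunk = 4096L) {
  fs <- rec$fs
  win_n <- params$window_s * fs
  if (abs(win_n - round(win_n)) > 1e-9)
    stop("window_s * fs must be an integer number of samples")
  win_n <- as.integer(round(win_n))
  n <- length(rec$samples)
  if (n < win_n) stop("recording shorter than one analysis window")
  starts <- as.integer(round(seq(0, (n - win_n) / fs, by = params$step_s) * fs))
  starts <- starts[starts + win_n <= n]
  m <- length(starts)
  nfft <- max(params$min_nfft, 2^ceiling(log2(win_n)))
  nf <- nfft %/% 2 + 1
  tapers <- dpss_tapers(win_n, params$tw, params$n_tapers)
  power <- matrix(0, nrow = nf, ncol = m)
  scale <- c(1, rep(2, nf - 2), 1) / fs   # one-sided PSD scaling
  idx0 <- seq_len(win_n)
  for (lo in seq(1, m, by = chunk)) {
    hi <- min(lo + chunk - 1, m)
    cols <- lo:hi
    X <- matrix(rec$samples[rep(starts[cols], each = win_n) + idx0],
                nrow = win_n)
    if (params$detrend == "constant")
      X <- sweep(X, 2, colMeans(X))
    acc <- matrix(0, nrow = nf, ncol = length(cols))
    pad <- matrix(0, nrow = nfft, ncol = length(cols))
    for (k in seq_len(params$n_tapers)) {
      pad[idx0, ] <- X * tapers[, k]
      F <- stats::mvfft(pad)[seq_len(nf), , drop = FALSE]
      acc <- acc + Mod(F)^2
    }
    power[, cols] <- (acc / params$n_tapers) * scale
  }
  structure(list(times = rec$t0 + starts / fs + params$window_s / 2,
                 freqs = (seq_len(nf) - 1) * fs / nfft,
                 power = power, params = params, fs = fs),
            class = "tfs_spectrogram")
}

#' @export
print.tfs_spectrogram <- function(x, ...) {
  cat(sprintf("<tfs_spectrogram> %d freqs x %d times, %.3g-%.4g Hz, t %.2f-%.2f s\n",
              nrow(x$power), ncol(x$power), min(x$freqs), max(x$freqs),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Write a spectrogram as CSV plus a JSON sidecar
#'
#' @param spec a `tfs_spectrogram`.
#' @param path_csv CSV of the power matrix (rows = frequencies).
#' @param path_json sidecar with times, freqs and parameters.
#' @export
write_spectrogram <- function(spec, path_csv, path_json = NULL) {
  utils::write.table(spec$power, path_csv, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(times = spec$times, freqs = spec$freqs,
                              fs = spec$fs, params = unclass(spec$params)),
                         path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_csv)
}
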