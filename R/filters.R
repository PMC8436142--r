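#' Design a Butterworth filter in second-order sections
#'
#' Analog Butterworth prototype poles are frequency-transformed (low- or
#' high-pass) with bilinear pre-warping and discretized section by section,
#' so the digital filter is realized directly as a cascade of biquads and is
#' numerically stable at high orders.
#'
#' @param n filter order.
#' @param fc cutoff frequency (Hz, -3 dB point).
#' @param fs sampling rate (Hz).
#' @param type "high" or "low".
#' @return matrix with one row per section and columns b0,b1,b2,a1,a2
#'   (a0 normalized to 1).
#' @keywords internal
butter_sos <- function(n, fc, fs, type = c("high", "low")) {
  type <- match.arg(type)
  stopifnot(n >= 1, fc > 0, fc < fs / 2)
  wc <- 2 * fs * tan(pi * fc / fs)        # pre-warped analog cutoff (rad/s)
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-circle LHP poles
  if (type == "low") poles <- wc * proto else poles <- wc / proto
  # pair conjugates: take poles with Im >= 0; real pole (odd n) gives a
  # first-order section padded with zero coefficients
  sel <- poles[Im(poles) > 1e-9 * Mod(poles) | abs(Im(poles)) <= 1e-9 * Mod(poles)]
  sel <- sel[order(-Re(sel))]
  K <- 2 * fs
  sos <- matrix(0, nrow = length(sel), ncol = 5,
                dimnames = list(NULL, c("b0", "b1", "b2", "a1", "a2")))
  for (i in seq_along(sel)) {
    p <- sel[[i]]
    second <- abs(Im(p)) > 1e-9 * Mod(p)
    if (second) {
      a1s <- -2 * Re(p); a0s <- Mod(p)^2
      if (type == "low") { b2s <- 0; b1s <- 0; b0s <- a0s } else { b2s <- 1; b1s <- 0; b0s <- 0 }
      # bilinear transform of (b2 s^2 + b1 s + b0)/(s^2 + a1 s + a0)
      den <- c(K^2 + a1s * K + a0s, 2 * a0s - 2 * K^2, K^2 - a1s * K + a0s)
      num <- c(b2s * K^2 + b1s * K + b0s, 2 * b0s - 2 * b2s * K^2,
               b2s * K^2 - b1s * K + b0s)
    } else {
      a0s <- -Re(p)
      if (type == "low") { b1s <- 0; b0s <- a0s } else { b1s <- 1; b0s <- 0 }
      den <- c(K + a0s, a0s - K, 0)
      num <- c(b1s * K + b0s, b0s - b1s * K, 0)
    }
    sos[i, ] <- c(num / den[1], den[2:3] / den[1])
  }
  sos
}

#' Apply one cascade of biquads in one direction
#' @keywords internal
sosfilt <- function(sos, x) {
  n <- length(x)
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:5]
    y <- b[1] * x + b[2] * c(0, x[-n]) + b[3] * c(0, 0, x[-c(n - 1, n)])
    if (any(a != 0)) y <- stats::filter(y, -a, method = "recursive")
    x <- as.numeric(y)
  }
  x
}

#' Zero-phase filtering (forward-backward) with odd-reflection padding
#' @keywords internal
sosfiltfilt <- function(sos, x) {
  n <- length(x)
  pad <- min(n - 1, 1000L)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xe <- c(left, x, right)
  y <- sosfilt(sos, xe)
  y <- rev(sosfilt(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-pass via cascaded high- and low-pass Butterworth sections
#' @keywords internal
bandpass_filtfilt <- function(x, fs, f_lo, f_hi, order = 4) {
  hp <- butter_sos(order, f_lo, fs, "high")
  lp <- butter_sos(order, f_hi, fs, "low")
  sosfiltfilt(rbind(hp, lp), x)
}

#' Analytic-signal amplitude via the FFT Hilbert transform
#' @keywords internal
hilbert_amplitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Centered moving average; edges use the partial-window mean
#' @keywords internal
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - half - 1L), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
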