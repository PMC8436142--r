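#' Synthetic sleep-EEG configuration
#'
#' The generator emulates the phenomenology the detectors are built for:
#' 1/f (pink) background noise, a slow sinusoidal component during N2/N3,
#' transient Gaussian-windowed sigma-range bursts placed by a Poisson
#' process during N2 (with a two-component amplitude model so that a
#' high-amplitude subset mimics traditional spindles while the full set
#' mimics the broader sigma-peak class), and occasional high-amplitude
#' broadband artifacts.
#'
#' @param fs sampling rate (Hz).
#' @param duration_min total recording length (minutes, >= 5).
#' @param burst_rate_per_min Poisson burst rate during N2 (events/min).
#' @param frac_high_amp fraction of bursts in the high-amplitude component.
#' @param freq_mean,freq_sd burst frequency distribution (Hz), truncated to
#'   10-16 Hz.
#' @param dur_lognorm_mu,dur_lognorm_sigma log-normal duration parameters
#'   (log-seconds), truncated to 0.3-3 s.
#' @param amp_low,amp_high envelope peak amplitudes of the two components
#'   (µV).
#' @param background pink-noise SD (µV).
#' @param so_amp slow-oscillation (0.8 Hz) amplitude during N2/N3 (µV).
#' @param artifact_rate_per_hour rate of injected broadband transients.
#' @param amp_mode `"nested"` (two-component) or `"continuum"` (log-normal
#'   envelope across the two components' range) amplitude model.
#' @param stage_blocks data frame with columns `stage`, `minutes` defining
#'   the repeating stage schedule; default cycles W/N2/N3 with mostly N2.
#' @param seed integer RNG seed.
#' @export
synth_config <- function(fs = 100, duration_min = 60, burst_rate_per_min = 10,
                         frac_high_amp = 1 / 3, freq_mean = 13, freq_sd = 1,
                         dur_lognorm_mu = log(0.8), dur_lognorm_sigma = 0.4,
                         amp_low = 5, amp_high = 15, background = 15,
                         so_amp = 40, artifact_rate_per_hour = 2,
                         amp_mode = c("nested", "continuum"),
                         stage_blocks = NULL, seed = 1L) {
  amp_mode <- match.arg(amp_mode)
  if (duration_min < 5) stop("duration_min must be at least 5 minutes")
  stopifnot(burst_rate_per_min >= 0, frac_high_amp >= 0, frac_high_amp <= 1,
            amp_low >= 0, amp_high >= 0, background >= 0)
  if (is.null(stage_blocks))
    stage_blocks <- data.frame(stage = c("W", "N2", "N3"),
                               minutes = c(2, 20, 3))
  structure(list(fs = fs, duration_min = duration_min,
                 burst_rate_per_min = burst_rate_per_min,
                 frac_high_amp = frac_high_amp, freq_mean = freq_mean,
                 freq_sd = freq_sd, dur_lognorm_mu = dur_lognorm_mu,
                 dur_lognorm_sigma = dur_lognorm_sigma, amp_low = amp_low,
                 amp_high = amp_high, background = background,
                 so_amp = so_amp,
                 artifact_rate_per_hour = artifact_rate_per_hour,
                 amp_mode = amp_mode, stage_blocks = stage_blocks,
                 seed = as.integer(seed)),
            class = "tfs_synth_config")
}

# 1/f amplitude-shaped Gaussian noise, scaled to the requested SD
pink_noise <- function(n, sd_target) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))               # avoid division by zero at DC
  f <- pmin(f, n - f + 1)                 # mirror for negative frequencies
  X <- X / sqrt(f)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x) * sd_target
}

rtrunc <- function(n, rfun, lo, hi, ...) {
  out <- rfun(n, ...)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rfun(length(bad), ...)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Generate a synthetic recording with ground truth
#'
#' Deterministic given `config$seed`.  Bursts are Gaussian-windowed
#' sinusoids; the ground-truth duration is the full width at half maximum
#' of the envelope (SD = duration/2.355), the standard Gaussian width
#' convention, so stated durations are commensurate with the
#' half-prominence widths measured downstream.  Placement is Poisson
#' within N2 with overlap rejection (0.5 s minimum gap between stated
#' intervals); artifacts are 0.5 s broadband 500 µV transients.
#'
#' @param config a [synth_config()].
#' @return list with `recording` (a [recording()]) and `truth`: a list of
#'   `events` (event table with `frequency_hz`, `amplitude_uv`,
#'   `component` columns), `artifacts` (interval data frame) and
#'   `hypnogram`.
#' @export
synth_generate <- function(config = synth_config()) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration_min * 60 * fs)
  # stage schedule: repeat the block table until the recording is covered
  blocks <- config$stage_blocks
  epochs <- character(0)
  while (length(epochs) * 30 < config$duration_min * 60) {
    for (b in seq_len(nrow(blocks)))
      epochs <- c(epochs, rep(blocks$stage[b], round(blocks$minutes[b] * 2)))
  }
  epochs <- epochs[seq_len(ceiling(config$duration_min * 2))]
  hyp <- hypnogram(epochs, epoch_s = 30)
  stage <- stage_per_sample(hyp, n, fs)
  t <- (seq_len(n) - 1) / fs
  x <- pink_noise(n, config$background)
  nrem <- stage %in% c("N2", "N3")
  x[nrem] <- x[nrem] + config$so_amp * sin(2 * pi * 0.8 * t[nrem])
  # --- bursts, Poisson-placed in N2 with overlap rejection -------------
  n2_min <- stage_minutes(hyp, "N2")
  n_burst <- stats::rpois(1, config$burst_rate_per_min * n2_min)
  n2_samples <- which(stage == "N2")
  placed <- data.frame(start_s = numeric(), end_s = numeric(),
                       frequency_hz = numeric(), amplitude_uv = numeric(),
                       component = character())
  attempts <- 0
  while (nrow(placed) < n_burst && attempts < 50 * n_burst) {
    attempts <- attempts + 1
    dur <- rtrunc(1, stats::rlnorm, 0.3, 3, meanlog = config$dur_lognorm_mu,
                  sdlog = config$dur_lognorm_sigma)
    ctr_i <- sample(n2_samples, 1)
    st <- ctr_i / fs - dur / 2
    en <- st + dur
    lo_i <- floor(st * fs) + 1
    hi_i <- ceiling(en * fs)
    if (lo_i < 1 || hi_i > n) next
    if (!all(stage[lo_i:hi_i] == "N2")) next
    if (nrow(placed) &&
        any(placed$start_s < en + 0.5 & placed$end_s > st - 0.5)) next
    f <- rtrunc(1, stats::rnorm, 10, 16, mean = config$freq_mean,
                sd = config$freq_sd)
    if (config$amp_mode == "nested") {
      high <- stats::runif(1) < config$frac_high_amp
      amp <- if (high) config$amp_high else config$amp_low
      comp <- if (high) "high" else "low"
    } else {
      mu <- mean(log(c(config$amp_low, config$amp_high)))
      amp <- rtrunc(1, stats::rlnorm, config$amp_low / 2, config$amp_high * 2,
                    meanlog = mu, sdlog = 0.5)
      comp <- if (amp >= exp(mu)) "high" else "low"
    }
    tc <- (st + en) / 2
    sigma <- dur / 2.355                     # stated duration = FWHM
    wlo <- max(1L, floor((tc - 3.5 * sigma) * fs) + 1L)
    whi <- min(n, ceiling((tc + 3.5 * sigma) * fs))
    tt <- t[wlo:whi]
    env <- amp * exp(-(tt - tc)^2 / (2 * sigma^2))
    phase <- stats::runif(1, 0, 2 * pi)
    x[wlo:whi] <- x[wlo:whi] + env * sin(2 * pi * f * (tt - tc) + phase)
    placed <- rbind(placed, data.frame(start_s = st, end_s = en,
                                       frequency_hz = f, amplitude_uv = amp,
                                       component = comp))
  }
  if (nrow(placed) < n_burst)
    stop("burst placement saturated: rate x duration too dense")
  placed <- placed[order(placed$start_s), , drop = FALSE]
  # --- artifacts -------------------------------------------------------
  n_art <- stats::rpois(1, config$artifact_rate_per_hour *
                          config$duration_min / 60)
  art <- data.frame(start_s = numeric(), end_s = numeric())
  for (i in seq_len(n_art)) {
    st <- stats::runif(1, 0, config$duration_min * 60 - 0.5)
    lo_i <- floor(st * fs) + 1
    hi_i <- min(n, lo_i + round(0.5 * fs) - 1)
    x[lo_i:hi_i] <- x[lo_i:hi_i] + stats::rnorm(hi_i - lo_i + 1, sd = 500)
    art <- rbind(art, data.frame(start_s = st, end_s = hi_i / fs))
  }
  events <- event_table(start_s = placed$start_s, end_s = placed$end_s,
                        method = "truth", subject = "synthetic", night = 1L,
                        frequency_hz = placed$frequency_hz,
                        amplitude_uv = placed$amplitude_uv,
                        component = placed$component)
  list(recording = recording(x, fs, channel = "SYNTH-C3"),
       truth = list(events = events, artifacts = art, hypnogram = hyp))
}

#' Write a synthetic fixture to disk
#'
#' Produces an EDF signal file, a plain-text hypnogram and a ground-truth
#' event CSV, all loadable through the package's readers.
#'
#' @param rec a [recording()].
#' @param truth the `truth` element of [synth_generate()].
#' @param dir writable output directory.
#' @return named character vector of the files written.
#' @export
write_fixture <- function(rec, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(edf = file.path(dir, "recording.edf"),
             hypnogram = file.path(dir, "hypnogram.txt"),
             events = file.path(dir, "ground_truth.csv"))
  write_edf(rec, paths["edf"])
  write_hypnogram(truth$hypnogram, paths["hypnogram"])
  write_event_table(truth$events, paths["events"])
  paths
}
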