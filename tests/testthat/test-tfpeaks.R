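test_that("frequency step measures prominence of a constructed bump", {
  freqs <- seq(0, 50, by = 0.25)
  # closed form: flat 10 dB baseline, 6 dB Gaussian bump at 13 Hz
  col <- 10 + 6 * exp(-(freqs - 13)^2 / (2 * 0.8^2))
  db <- matrix(col, ncol = 5, nrow = length(freqs))
  sp <- spec_from_db(db, freqs, times = seq(0.5, by = 0.05, length.out = 5))
  tr <- frequency_step(sp, c(9, 17))
  expect_equal(tr$value, rep(6, 5), tolerance = 0.1 / 6)
  expect_lt(max(abs(tr$freq_at - 13)), 0.25 + 1e-12)
  # half-prominence spectral width of the Gaussian: 2*sigma*sqrt(2 ln 2)
  expect_equal(tr$band_at[1], 2 * 0.8 * sqrt(2 * log(2)), tolerance = 0.1)
})

test_that("monotone columns yield zero prominence", {
  freqs <- seq(0, 50, by = 0.5)
  db <- matrix(seq(20, 0, length.out = length(freqs)), ncol = 3,
               nrow = length(freqs))
  sp <- spec_from_db(db, freqs, times = c(0.5, 0.55, 0.6))
  tr <- frequency_step(sp, c(9, 17))
  expect_equal(tr$value, rep(0, 3))
})

test_that("the larger-prominence bump wins", {
  freqs <- seq(0, 50, by = 0.25)
  col <- 10 + 5 * exp(-(freqs - 12)^2 / (2 * 0.6^2)) +
    3 * exp(-(freqs - 15)^2 / (2 * 0.6^2))
  sp <- spec_from_db(matrix(col, ncol = 2, nrow = length(freqs)),
                     freqs, times = c(0.5, 0.55))
  tr <- frequency_step(sp, c(9, 17))
  expect_lt(abs(tr$freq_at[1] - 12), 0.3)
})

test_that("f_range outside the grid errors", {
  freqs <- seq(0, 20, by = 0.5)
  sp <- spec_from_db(matrix(0, length(freqs), 2), freqs, c(0.5, 0.55))
  expect_error(frequency_step(sp, c(9, 25)), "outside")
})

test_that("time step turns pulses into peaks with half-prominence bounds", {
  mk_trace <- function(v) {
    structure(list(times = seq(0.5, by = 0.05, length.out = length(v)),
                   value = v, freq_at = rep(13, length(v)),
                   band_at = rep(3, length(v)), step_s = 0.05),
              class = "tfs_prom_trace")
  }
  # single triangular pulse -> one peak
  tri <- c(rep(0, 5), seq(0, 6, by = 1), seq(5, 0, by = -1), rep(0, 5))
  pk <- time_step(mk_trace(tri))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$prominence_db, 6)
  expect_equal(pk$central_freq, 13)
  # half-prominence crossings at value 3, linear flanks => width 6 steps
  expect_equal(pk$duration_s, 6 * 0.05, tolerance = 1e-9)
  # constant trace -> no peaks
  expect_equal(nrow(time_step(mk_trace(rep(4, 30)))), 0)
  # two pulses with a zero valley -> two disjoint peaks
  two <- c(tri, tri)
  pk2 <- time_step(mk_trace(two))
  expect_equal(nrow(pk2), 2)
  expect_lt(pk2$t_hi[1], pk2$t_lo[2])
})

test_that("most prominent peak in an interval is selected with tie-breaks", {
  pks <- data.frame(t_peak = c(1, 2, 3), t_lo = c(0.8, 1.8, 2.8),
                    t_hi = c(1.2, 2.2, 3.2), prominence_db = c(3, 7, 5),
                    duration_s = 0.4, central_freq = c(12, 13, 14),
                    f_lo = 11, f_hi = 15, bandwidth_hz = 4)
  expect_equal(most_prominent_in_interval(0, 4, pks)$prominence_db, 7)
  expect_null(most_prominent_in_interval(5, 6, pks))
  pks$prominence_db <- c(7, 7, 5)         # tie -> earlier t_peak
  expect_equal(most_prominent_in_interval(0, 4, pks)$t_peak, 1)
})

test_that("two-step extraction matches the exhaustive 2-D oracle on patches", {
  set.seed(31)
  for (rep in 1:8) {
    nf <- sample(20:50, 1); nt <- sample(20:50, 1)
    db <- matrix(rnorm(nf * nt, 10, 3), nf, nt)
    freqs <- seq(5, by = 0.5, length.out = nf)
    sp <- spec_from_db(db, freqs, times = seq(0.5, by = 0.05, length.out = nt))
    lo <- freqs[5]; hi <- freqs[nf - 4]
    tr <- frequency_step(sp, c(lo, hi))
    orc <- oracle_two_step(db, row_lo = 5, row_hi = nf - 4)
    expect_equal(tr$value, orc$trace, tolerance = 1e-12)
    pk <- time_step(tr)
    expect_equal(match(round(pk$t_peak, 6), round(tr$times, 6)),
                 orc$apex_cols)
  }
})

test_that("prominence and bounds are invariant to power scaling", {
  sim <- small_night()
  sp <- sim$spec
  tr1 <- frequency_step(sp)
  sp2 <- sp
  sp2$power <- sp2$power * 37.5
  tr2 <- frequency_step(sp2)
  expect_equal(tr1$value, tr2$value, tolerance = 1e-10)
  expect_equal(tr1$freq_at, tr2$freq_at)
  pk1 <- time_step(tr1); pk2 <- time_step(tr2)
  expect_equal(pk1$t_lo, pk2$t_lo, tolerance = 1e-9)
  expect_equal(pk1$central_freq, pk2$central_freq)
})

test_that("a high-SNR injected burst is recovered as one well-formed peak", {
  set.seed(32)
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- tfsigma:::pink_noise(length(t), 10)
  sigma <- 1 / 2.355                       # 1 s FWHM burst at t=30, 13 Hz
  x <- x + 30 * exp(-(t - 30)^2 / (2 * sigma^2)) * sin(2 * pi * 13 * (t - 30))
  sp <- compute_spectrogram(recording(x, fs))
  pk <- filter_candidates(time_step(frequency_step(sp)))
  inside <- pk[pk$t_peak > 29 & pk$t_peak < 31.5, ]
  strong <- inside[inside$prominence_db > max(pk$prominence_db) / 2, ]
  expect_equal(nrow(strong), 1)
  expect_lt(abs(strong$central_freq - 13), 1)
  expect_lt(abs(strong$duration_s - 1), 0.3)
})
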