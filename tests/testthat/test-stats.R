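test_that("event selection enforces stage, buffer and frequency rules", {
  hyp <- hypnogram(c("N2", "N2", "N2", "N2", "W", "N2"))   # W at 120-150 s
  fs <- 100
  n <- 180 * fs
  mask <- intervals_to_mask(data.frame(start_s = 50, end_s = 51), n, fs)
  events <- ev(c(10, 46.5, 60, 100, 155),
               c(11, 47.5, 61, 101, 156),
               central_freq_hz = c(13, 13, 9.5, 12, 13))
  out <- select_events(events, hyp, mask)
  # 10-11: clean N2, 13 Hz -> kept
  # 46.5-47.5: ends 2.5 s before the artifact at 50 -> removed (within buffer)
  # 60-61: central 9.5 Hz -> removed
  # 100-101: within 3 s of W at 120? no (19 s away) -> kept
  # 155-156: inside W-adjacent N2 but 5 s after W ends -> kept
  expect_equal(out$start_s, c(10, 100, 155))
  # tighten: an event ending 2 s before the W stage is removed
  ev2 <- ev(117, 118, central_freq_hz = 13)
  expect_equal(nrow(select_events(ev2, hyp, mask)), 0)
})

test_that("f1_score reproduces printed worked examples", {
  expect_equal(round(f1_score(0.89, 0.43), 2), 0.58)
  expect_equal(round(f1_score(0.91, 0.90), 2), 0.90)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
})

test_that("f1 is dominated by its arguments (property)", {
  set.seed(61)
  p <- runif(200); r <- runif(200)
  f <- f1_score(p, r)
  expect_true(all(f <= 2 * pmin(p, r) + 1e-12))
  expect_true(all(f <= pmax(p, r) + 1e-12))
})

test_that("match_events handles the canonical toy cases", {
  a <- ev(c(0, 2), c(1, 3))
  b <- ev(0.5, 2.5)
  cs <- match_events(a, b, fs = 100)
  expect_equal(c(cs$tp, cs$fp, cs$fn), c(1, 0, 0))
  expect_equal(c(cs$precision, cs$recall), c(1, 1))

  a2 <- ev(0, 1)
  b2 <- ev(c(0.2, 0.7), c(0.6, 1.4))
  cs2 <- match_events(a2, b2, fs = 100)
  expect_equal(c(cs2$tp, cs2$fp), c(2, 0))
  expect_equal(c(cs2$precision, cs2$recall), c(1, 1))

  ident <- ev(c(1, 5, 9), c(2, 6, 10))
  cs3 <- match_events(ident, ident, fs = 100)
  expect_equal(c(cs3$precision, cs3$recall, cs3$f1), c(1, 1, 1))
  expect_equal(cs3$mean_overlap_pct, 100)

  cs4 <- match_events(ident, ident[0, ], fs = 100)
  expect_true(is.nan(cs4$precision))
  expect_equal(cs4$f1, 0)
  expect_error(match_events(ident[0, ], ident, fs = 100), "nonempty")
})

test_that("match_events equals the all-pairs oracle on random sets (property)", {
  set.seed(62)
  for (i in 1:40) {
    nr <- sample(1:30, 1); no <- sample(0:30, 1)
    mk <- function(n) {
      st <- runif(n, 0, 60)
      ev(st, st + runif(n, 0.2, 3))
    }
    a <- mk(nr); b <- mk(no)
    got <- match_events(a, b, fs = 100)
    orc <- oracle_match(a, b)
    expect_equal(got$tp, orc$tp)
    expect_equal(got$fp, orc$fp)
    expect_equal(got$fn, orc$fn)
    expect_equal(got$recall, orc$recall)
    if (no > 0) expect_equal(got$precision, orc$precision)
  }
})

test_that("overlap percentage is symmetric for one-to-one matches", {
  set.seed(63)
  st <- sort(runif(10, 0, 100))
  a <- ev(st, st + 1)
  b <- ev(st + 0.3, st + 1.4)
  o1 <- match_events(a, b, fs = 100)$mean_overlap_pct
  o2 <- match_events(b, a, fs = 100)$mean_overlap_pct
  expect_equal(o1, o2)
})

test_that("median property tests detect a constructed shift", {
  set.seed(64)
  subs <- paste0("s", 1:6)
  base <- do.call(rbind, lapply(subs, function(s) {
    st <- sort(runif(40, 0, 500))
    ev(st, st + 1, subject = s, prominence_db = rlnorm(40, 2, 0.3),
       duration_s = runif(40, 0.3, 2), central_freq_hz = runif(40, 10, 16),
       bandwidth_hz = runif(40, 2, 5))
  }))
  same <- median_property_tests(base, base)
  expect_true(all(same$effect == 0))
  expect_true(all(same$p == 1))

  shifted <- base
  shifted$prominence_db <- shifted$prominence_db + 3
  res <- median_property_tests(base, shifted)
  prom <- res[res$property == "prominence_db", ]
  expect_equal(prom$effect, 3, tolerance = 1e-9)
  expect_lt(prom$p, 0.01)

  two <- base[base$subject %in% subs[1:2], ]
  expect_warning(median_property_tests(two, two), "df = 1")
  expect_error(median_property_tests(base, base[base$subject != "s1", ]),
               "match")
})

test_that("binwise rates conserve counts and flag constructed enrichment", {
  set.seed(65)
  subs <- paste0("s", 1:6)
  n2min <- stats::setNames(rep(30, 6), subs)
  base <- do.call(rbind, lapply(subs, function(s) {
    st <- sort(runif(60, 0, 1500))
    ev(st, st + 1, subject = s, prominence_db = rnorm(60, 10, 2),
       duration_s = runif(60, 0.3, 2), central_freq_hz = runif(60, 10, 16),
       bandwidth_hz = runif(60, 2, 5))
  }))
  same <- binwise_rate_tests(base, base, anchor = "a", n2_minutes = n2min)
  expect_true(all(vapply(same$properties, function(p) all(p$p_values == 1), TRUE)))
  # conservation: rates x minutes recover each subject's event count
  r <- same$properties$prominence_db$rates
  for (s in subs)
    expect_equal(sum(r[s, "a", ]) * n2min[[s]], sum(base$subject == s))

  # enrich method b with low-prominence events in every subject
  extra <- do.call(rbind, lapply(subs, function(s) {
    st <- sort(runif(40, 0, 1500))
    med <- stats::median(base$prominence_db[base$subject == s])
    sdv <- stats::sd(base$prominence_db[base$subject == s])
    ev(st, st + 1, subject = s, prominence_db = med - runif(40, 1.2, 2.2) * sdv,
       duration_s = runif(40, 0.3, 2), central_freq_hz = runif(40, 10, 16),
       bandwidth_hz = runif(40, 2, 5))
  }))
  enriched <- rbind(base, extra)
  res <- binwise_rate_tests(base, enriched, anchor = "a", n2_minutes = n2min)
  pv <- res$properties$prominence_db$p_values
  expect_true(all(pv[2:3] < 0.05))        # bins centred at -2 and -1 SD
  expect_true(all(pv[5:7] > 0.05))        # no enrichment at positive z

  # open-ended outer bins
  cuts <- cut(c(-3, -2.4, 2.6, 9), res$bin_edges)
  expect_equal(as.integer(cuts), c(1, 2, 7, 7))
})

test_that("aggregate event spectrograms align troughs and resist outliers", {
  set.seed(66)
  fs <- 100
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  x <- tfsigma:::pink_noise(length(t), 2)
  centers <- seq(10, 106, by = 12)
  for (tc in centers)
    x <- x + 20 * exp(-(t - tc)^2 / (2 * 0.4^2)) * sin(2 * pi * 13 * (t - tc))
  rec <- recording(x, fs)
  spec <- compute_spectrogram(rec)
  events <- ev(centers - 0.75, centers + 0.75)
  agg <- aggregate_event_spectrogram(rec, events, spec)
  peak_idx <- which(agg$power_db == max(agg$power_db), arr.ind = TRUE)
  # the pink background tilts the dB image slightly; 1 Hz is well within the
  # 4 Hz spectral resolution of the estimator
  expect_lt(abs(agg$freqs[peak_idx[1]] - 13), 1)
  expect_lt(abs(agg$rel_times[peak_idx[2]]), 0.2)

  # median of one event equals that event's own window
  one <- aggregate_event_spectrogram(rec, events[3, ], spec)
  ci <- which.min(abs(spec$times - centers[3]))
  # trough is near the event center; window columns must come from spec
  expect_equal(dim(one$power_db), c(length(spec$freqs), 61))

  # one saturated window barely moves the median
  x2 <- x
  bad <- t >= 50 & t < 53
  x2[bad] <- x2[bad] + rnorm(sum(bad), sd = 200)
  rec2 <- recording(x2, fs)
  spec2 <- compute_spectrogram(rec2)
  ev10 <- ev(c(centers - 0.75, 50.25), c(centers + 0.75, 51.75))
  agg9 <- aggregate_event_spectrogram(rec2, ev(centers - 0.75, centers + 0.75),
                                      spec2)
  agg10 <- aggregate_event_spectrogram(rec2, ev10, spec2)
  sig <- agg9$power_db > quantile(agg9$power_db, 0.95)
  expect_lt(stats::median(abs(agg10$power_db[sig] - agg9$power_db[sig])), 0.75)

  # events at the record edge are dropped with a warning
  expect_warning(aggregate_event_spectrogram(rec, ev(c(0.2, centers[2] - 0.75),
                                                     c(1.2, centers[2] + 0.75)),
                                             spec), "dropped")
})

test_that("night stability: identical nights give rho 1 and a null difference", {
  set.seed(67)
  subs <- paste0("s", 1:17)
  r1 <- runif(17, 2, 12)
  rates <- rbind(
    data.frame(subject = subs, night = 1, method = "tfsigma", rate = r1),
    data.frame(subject = subs, night = 2, method = "tfsigma", rate = r1),
    data.frame(subject = subs, night = 1, method = "spindle", rate = r1 / 3),
    data.frame(subject = subs, night = 2, method = "spindle", rate = r1 / 3))
  res <- night_stability(rates, n_perm = 200, seed = 1)
  expect_equal(unname(res$rho), c(1, 1), tolerance = 1e-12)
  expect_equal(res$observed_diff, 0, tolerance = 1e-12)
  expect_gt(res$perm_p, 0.5)
  expect_equal(unname(res$slope["tfsigma"]), 1, tolerance = 1e-9)

  # permutation p resolution with n_perm = 10
  res10 <- night_stability(rates, n_perm = 10, seed = 2)
  expect_true(res10$perm_p %in% seq(0, 1, by = 0.1))
})

test_that("night stability distinguishes a stable from an unstable method", {
  set.seed(68)
  mk <- function(rho, n = 17) {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    cbind(z1, z2)
  }
  reject <- logical(40)
  for (i in 1:40) {
    a <- mk(0.95); b <- mk(0.6)
    subs <- paste0("s", 1:17)
    rates <- rbind(
      data.frame(subject = subs, night = 1, method = "m1", rate = 10 + a[, 1]),
      data.frame(subject = subs, night = 2, method = "m1", rate = 10 + a[, 2]),
      data.frame(subject = subs, night = 1, method = "m2", rate = 3 + b[, 1]),
      data.frame(subject = subs, night = 2, method = "m2", rate = 3 + b[, 2]))
    res <- night_stability(rates, n_perm = 99, seed = i)
    reject[i] <- res$perm_p <= 0.05
  }
  expect_gte(mean(reject), 0.5)
})
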