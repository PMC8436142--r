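#' Stage- and artifact-based event selection
#'
#' Keeps events that lie fully inside N2 sleep and have no artifact or
#' non-N2 sample within `buffer_s` seconds of `[start_s, end_s)` (clipped
#' at the record edges), mirroring the usual guard against partial events
#' near stage transitions and artifacts.  When a `central_freq_hz` column
#' is present, events outside `f_range` are also removed.
#'
#' @param events an event table.
#' @param hyp a [hypnogram()].
#' @param mask optional `tfs_artifact_mask`.
#' @param fs sampling rate of the underlying recording (Hz); taken from
#'   `mask` when present.
#' @param n_samples recording length in samples; inferred from the
#'   hypnogram when missing.
#' @param f_range central-frequency band to retain (Hz).
#' @param buffer_s guard interval (s, default 3).
#' @export
select_events <- function(events, hyp, mask = NULL, fs = NULL,
                          n_samples = NULL, f_range = c(10, 16),
                          buffer_s = 3) {
  if (is.null(fs)) {
    if (!is.null(mask)) fs <- mask$fs
    else stop("fs is required when no mask is given")
  }
  if (is.null(n_samples)) {
    n_samples <- if (!is.null(mask)) length(mask$mask)
    else round(length(hyp$stages) * hyp$epoch_s * fs)
  }
  stage <- stage_per_sample(hyp, n_samples, fs)
  bad <- stage != "N2"
  if (!is.null(mask)) bad <- bad | mask$mask
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    lo <- max(1L, floor((events$start_s[i] - buffer_s) * fs) + 1L)
    hi <- min(n_samples, ceiling((events$end_s[i] + buffer_s) * fs))
    inside_lo <- max(1L, floor(events$start_s[i] * fs) + 1L)
    inside_hi <- min(n_samples, ceiling(events$end_s[i] * fs))
    keep[i] <- inside_lo <= inside_hi && !any(bad[lo:hi])
  }
  if ("central_freq_hz" %in% names(events)) {
    cf <- events$central_freq_hz
    keep <- keep & (is.na(cf) | (cf >= f_range[1] & cf <= f_range[2]))
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall values in `[0, 1]`; `(0, 0)` returns 0 by
#'   convention, and NaN precision (no detections) also yields 0.
#' @export
f1_score <- function(precision, recall) {
  out <- 2 * precision * recall / (precision + recall)
  out[!is.finite(out)] <- 0
  out
}

# Half-open interval -> sample index set on the fs grid
interval_samples <- function(start_s, end_s, fs) {
  lo <- floor(start_s * fs)
  hi <- ceiling(end_s * fs) - 1
  if (hi < lo) hi <- lo
  lo:hi
}

#' Event-based confusion statistics with interval overlap
#'
#' Matching is asymmetric, following the event-based semantics of
#' reference-anchored detector evaluation: on the detector side, every
#' `other` event overlapping at least one reference event counts as one
#' true positive (so several detections on one reference each count, while
#' one detection spanning several references counts once); `other` events
#' with no overlap are false positives, and precision = TP/(TP+FP).  On
#' the reference side, reference events with no overlapping detection are
#' false negatives and recall is the fraction of reference events
#' overlapped.  F1 is the harmonic mean.  For every overlapping
#' (detection, reference) pair the overlap percentage is the
#' intersection-over-union of covered sample points on the `fs` grid;
#' `mean_overlap_pct` averages it over those pairs.
#'
#' @param reference,other event tables on the same time base.
#' @param fs sampling rate defining the sample grid for overlap (Hz).
#' @return list of class `tfs_confusion`: `tp`, `fp`, `fn`, `precision`
#'   (NaN when there are no detections), `recall`, `f1`,
#'   `mean_overlap_pct` (NA when there are no TP pairs).
#' @export
match_events <- function(reference, other, fs = 100) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("reference event table must be nonempty")
  nr <- nrow(reference); no <- nrow(other)
  ov <- matrix(FALSE, nr, no)
  if (no > 0)
    for (i in seq_len(nr))
      ov[i, ] <- other$start_s < reference$end_s[i] &
        other$end_s > reference$start_s[i]
  det_hit <- if (no) colSums(ov) > 0 else logical(0)
  ref_hit <- rowSums(ov) > 0
  tp <- sum(det_hit)
  fp <- sum(!det_hit)
  fn <- sum(!ref_hit)
  precision <- if (no == 0) NaN else tp / (tp + fp)
  recall <- sum(ref_hit) / nr
  ious <- c()
  for (j in which(det_hit)) {
    sj <- interval_samples(other$start_s[j], other$end_s[j], fs)
    for (i in which(ov[, j])) {
      si <- interval_samples(reference$start_s[i], reference$end_s[i], fs)
      ious <- c(ious, length(intersect(si, sj)) / length(union(si, sj)))
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1_score(precision, recall),
                 mean_overlap_pct = if (length(ious)) mean(ious) * 100 else NA_real_),
            class = "tfs_confusion")
}

#' @export
print.tfs_confusion <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  precision=%.3f recall=%.3f F1=%.3f overlap=%.1f%%\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1,
              x$mean_overlap_pct))
  invisible(x)
}

PROPERTY_COLS <- c("prominence_db", "duration_s", "central_freq_hz",
                   "bandwidth_hz")

#' Paired t-tests on per-subject property medians
#'
#' For each peak property present in both tables, per-subject medians are
#' computed for each method and compared with a paired-sample t-test
#' across subjects; the effect size is the mean of the paired median
#' differences (method b minus method a).
#'
#' @param events_a,events_b event tables with property columns and a
#'   `subject` column; every subject must appear in both.
#' @return data frame with columns `property`, `t`, `p`, `effect`
#'   (mean paired difference, b - a), `n_subjects`.
#' @export
median_property_tests <- function(events_a, events_b) {
  subs <- sort(unique(events_a$subject))
  if (!setequal(subs, unique(events_b$subject)))
    stop("subjects must match between the two tables")
  if (length(subs) < 2) stop("need at least 2 subjects for a paired test")
  if (length(subs) == 2) warning("only 2 subjects: paired t-test has df = 1")
  props <- intersect(PROPERTY_COLS, intersect(names(events_a), names(events_b)))
  res <- lapply(props, function(p) {
    ma <- vapply(subs, function(s)
      stats::median(events_a[[p]][events_a$subject == s], na.rm = TRUE), 0)
    mb <- vapply(subs, function(s)
      stats::median(events_b[[p]][events_b$subject == s], na.rm = TRUE), 0)
    d <- mb - ma
    degenerate <- stats::sd(d) < 1e-10 * max(1, abs(mean(d)))
    if (degenerate) {
      zero <- abs(mean(d)) < 1e-12
      tt <- list(statistic = if (zero) 0 else Inf,
                 p.value = if (zero) 1 else 0)
    } else {
      tt <- stats::t.test(mb, ma, paired = TRUE)
    }
    data.frame(property = p, t = unname(tt$statistic), p = tt$p.value,
               effect = mean(d), n_subjects = length(subs))
  })
  do.call(rbind, res)
}

#' Bin-wise event-rate tests on modified z-scored properties
#'
#' Per subject and property, the anchor method's events define the scale:
#' a modified z-score Z = (X - median)/SD (median for outlier robustness).
#' Both methods' property values are z-scored with that scale and binned
#' into seven fixed bins with edges (-Inf, -2.5, -1.5, -0.5, 0.5, 1.5,
#' 2.5, Inf) (width-1 bins centered at -2..2, open-ended extremes).  Bin
#' counts divided by N2 minutes give per-subject rates; a two-sided
#' Wilcoxon signed-rank test across subjects compares the two methods'
#' rates in each bin.
#'
#' @param events_a,events_b event tables with property and `subject`
#'   columns.
#' @param anchor `"a"` or `"b"`: which table anchors the z-scale.
#' @param n2_minutes named vector of N2 minutes per subject.
#' @return list of class `tfs_binwise` with `bin_edges` and, per property,
#'   `rates` (subject x method x bin array) and `p_values` (length 7).
#' @export
binwise_rate_tests <- function(events_a, events_b, anchor = c("a", "b"),
                               n2_minutes) {
  anchor <- match.arg(anchor)
  edges <- c(-Inf, -2.5, -1.5, -0.5, 0.5, 1.5, 2.5, Inf)
  subs <- sort(unique(c(events_a$subject, events_b$subject)))
  if (is.null(names(n2_minutes)))
    names(n2_minutes) <- subs[seq_along(n2_minutes)]
  props <- intersect(PROPERTY_COLS, intersect(names(events_a), names(events_b)))
  anchor_tab <- if (anchor == "a") events_a else events_b
  out <- list(bin_edges = edges, properties = list())
  for (p in props) {
    rates <- array(0, dim = c(length(subs), 2, 7),
                   dimnames = list(subs, c("a", "b"), NULL))
    for (si in seq_along(subs)) {
      s <- subs[si]
      av <- anchor_tab[[p]][anchor_tab$subject == s]
      ctr <- stats::median(av, na.rm = TRUE)
      scl <- stats::sd(av, na.rm = TRUE)
      if (!is.finite(scl) || scl == 0)
        stop("degenerate (zero-SD) anchor scale for subject ", s,
             ", property ", p)
      mins <- n2_minutes[[as.character(s)]]
      for (m in c("a", "b")) {
        v <- (if (m == "a") events_a else events_b)
        z <- (v[[p]][v$subject == s] - ctr) / scl
        cnt <- table(cut(z, edges, right = TRUE))
        rates[si, m, ] <- as.numeric(cnt) / mins
      }
    }
    pv <- vapply(1:7, function(b) {
      d <- rates[, "b", b] - rates[, "a", b]
      if (all(d == 0)) return(1)
      suppressWarnings(stats::wilcox.test(rates[, "b", b], rates[, "a", b],
                                          paired = TRUE)$p.value)
    }, 0)
    out$properties[[p]] <- list(rates = rates, p_values = pv)
  }
  class(out) <- "tfs_binwise"
  out
}

#' Trough-aligned aggregate event spectrogram
#'
#' Each event's central trough is the minimum of the 10-16 Hz band-passed
#' signal within `[start_s, end_s)`; the spectrogram columns within ±1.5 s
#' of the trough are extracted, and the element-wise median across events
#' is returned in dB.  Events whose window would cross the spectrogram
#' edge are dropped with a warning.
#'
#' @param rec the source [recording()].
#' @param events an event table (>= 1 row surviving the edge check).
#' @param spec the `tfs_spectrogram` of `rec`.
#' @param f_band alignment band-pass (Hz).
#' @param half_window_s half window around the trough (s).
#' @return list with `rel_times` (s, relative to trough), `freqs`, and
#'   `power_db` (frequency x relative-time matrix).
#' @export
aggregate_event_spectrogram <- function(rec, events, spec,
                                        f_band = c(10, 16),
                                        half_window_s = 1.5) {
  if (nrow(events) == 0) stop("need at least one event")
  filt <- bandpass_filtfilt(rec$samples, rec$fs, f_band[1], f_band[2])
  step <- spec$params$step_s
  nhalf <- round(half_window_s / step)
  slices <- list()
  dropped <- 0
  for (i in seq_len(nrow(events))) {
    idx <- interval_samples(events$start_s[i], events$end_s[i], rec$fs) + 1
    idx <- idx[idx >= 1 & idx <= length(filt)]
    trough_t <- rec$t0 + (idx[which.min(filt[idx])] - 0.5) / rec$fs
    ci <- which.min(abs(spec$times - trough_t))
    if (ci - nhalf < 1 || ci + nhalf > length(spec$times)) {
      dropped <- dropped + 1
      next
    }
    slices[[length(slices) + 1]] <- spec$power[, (ci - nhalf):(ci + nhalf)]
  }
  if (dropped > 0)
    warning(dropped, " event(s) too close to the record edge were dropped")
  if (!length(slices)) stop("no event window fits inside the spectrogram")
  arr <- array(unlist(slices), dim = c(dim(slices[[1]]), length(slices)))
  med <- apply(arr, c(1, 2), stats::median)
  list(rel_times = seq(-nhalf, nhalf) * step, freqs = spec$freqs,
       power_db = 10 * log10(pmax(med, 1e-300)))
}

#' Night-to-night rate stability with permutation testing
#'
#' For each method the Pearson correlation of night-1 versus night-2 event
#' rates across subjects is computed, together with a robust linear
#' regression (iteratively reweighted least squares with bisquare weights,
#' tuning constant 4.685) of night 2 on night 1 and a 95% CI on the slope.
#' The difference in correlations between the two methods is tested by
#' permutation: rates are z-scored within method, each subject's
#' (night1, night2) pair is randomly swapped between methods, and the
#' one-sided p-value is the fraction of permuted differences at least as
#' large as the observed one.
#'
#' @param rates data frame with columns `subject`, `night` (1/2), `method`,
#'   `rate`; every subject needs both nights for both methods.
#' @param n_perm permutation repetitions (default 10000).
#' @param seed optional RNG seed for the permutations.
#' @return list of class `tfs_stability`: per-method `rho`, `slope`,
#'   `slope_ci95`, plus `observed_diff` (first method minus second),
#'   `perm_p`, `n_perm`.
#' @export
night_stability <- function(rates, n_perm = 10000, seed = NULL) {
  methods <- unique(rates$method)
  if (length(methods) != 2) stop("exactly two methods are required")
  subs <- sort(unique(rates$subject))
  if (length(subs) < 3) stop("need at least 3 subjects for correlation")
  get <- function(m, n) {
    x <- rates[rates$method == m & rates$night == n, ]
    v <- x$rate[match(subs, x$subject)]
    if (anyNA(v)) stop("missing subject/night combination for method ", m)
    v
  }
  per_method <- lapply(methods, function(m) {
    n1 <- get(m, 1); n2 <- get(m, 2)
    fit <- MASS::rlm(n2 ~ n1, psi = MASS::psi.bisquare, c = 4.685,
                     maxit = 100)
    sm <- summary(fit)
    se <- sm$coefficients["n1", "Std. Error"]
    slope <- unname(stats::coef(fit)["n1"])
    list(rho = stats::cor(n1, n2), slope = slope,
         slope_ci95 = slope + c(-1, 1) * stats::qt(0.975, length(subs) - 2) * se,
         n1 = n1, n2 = n2)
  })
  names(per_method) <- methods
  z <- function(v) (v - mean(v)) / stats::sd(v)
  z1 <- lapply(per_method, function(pm) cbind(z(pm$n1), z(pm$n2)))
  obs <- stats::cor(z1[[1]][, 1], z1[[1]][, 2]) -
    stats::cor(z1[[2]][, 1], z1[[2]][, 2])
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  ns <- length(subs)
  null_d <- vapply(seq_len(n_perm), function(i) {
    swap <- stats::runif(ns) < 0.5
    a <- z1[[1]]; b <- z1[[2]]
    a2 <- a; a2[swap, ] <- b[swap, ]
    b2 <- b; b2[swap, ] <- a[swap, ]
    stats::cor(a2[, 1], a2[, 2]) - stats::cor(b2[, 1], b2[, 2])
  }, 0)
  structure(list(methods = methods,
                 rho = vapply(per_method, `[[`, 0, "rho"),
                 slope = vapply(per_method, `[[`, 0, "slope"),
                 slope_ci95 = lapply(per_method, `[[`, "slope_ci95"),
                 observed_diff = obs,
                 perm_p = mean(null_d >= obs), n_perm = n_perm),
            class = "tfs_stability")
}
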