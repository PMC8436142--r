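# Independent brute-force oracles, deliberately written with naive loops and
# kept free of the package's own peak/matching code paths.

# Local maxima of a series (strictly higher than the left neighbour; a
# plateau counts once, at its first sample, and must fall off on the right).
oracle_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j <= n - 1 && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[i]) out <- c(out, i)
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Topographic prominence of the peak at index i: height above the higher of
# the two flanking minima, each the lowest value between the peak and the
# nearest strictly higher sample (or the series edge).
oracle_prominence <- function(x, i) {
  h <- x[i]
  lmin <- h
  for (k in seq(i - 1, 1)) {
    if (x[k] > h) break
    lmin <- min(lmin, x[k])
  }
  rmin <- h
  for (k in seq(i + 1, length(x))) {
    if (x[k] > h) break
    rmin <- min(rmin, x[k])
  }
  h - max(lmin, rmin)
}

# Exhaustive 2-D search over a (freq x time) dB patch: per column the
# largest-prominence local maximum with apex in rows [row_lo, row_hi] (the
# "spectral winner"), then temporal local maxima of the winner-prominence
# trace.  Returns the trace and the set of (col, prominence) apexes.
oracle_two_step <- function(db, row_lo = 1, row_hi = nrow(db)) {
  nc <- ncol(db)
  w <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- db[, j]
    best <- 0
    for (i in oracle_local_maxima(col)) {
      if (i < row_lo || i > row_hi) next
      p <- oracle_prominence(col, i)
      if (p > best) best <- p
    }
    w[j] <- best
  }
  apex <- oracle_local_maxima(w)
  apex <- apex[vapply(apex, function(i) oracle_prominence(w, i) > 0, TRUE)]
  list(trace = w, apex_cols = apex)
}

# All-pairs interval matching oracle implementing the event-based TP/FP/FN
# semantics directly from the definitions.
oracle_match <- function(reference, other) {
  overlaps <- function(a1, a2, b1, b2) a1 < b2 && a2 > b1
  det_hit <- logical(nrow(other))
  for (j in seq_len(nrow(other)))
    for (i in seq_len(nrow(reference)))
      if (overlaps(reference$start_s[i], reference$end_s[i],
                   other$start_s[j], other$end_s[j])) det_hit[j] <- TRUE
  ref_hit <- logical(nrow(reference))
  for (i in seq_len(nrow(reference)))
    for (j in seq_len(nrow(other)))
      if (overlaps(reference$start_s[i], reference$end_s[i],
                   other$start_s[j], other$end_s[j])) ref_hit[i] <- TRUE
  tp <- sum(det_hit); fp <- sum(!det_hit); fn <- sum(!ref_hit)
  precision <- if (nrow(other) == 0) NaN else tp / (tp + fp)
  recall <- sum(ref_hit) / nrow(reference)
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall)
}

# Brute-force optimal contiguous split for 1-D two-class k-means.
oracle_kmeans2 <- function(x) {
  s <- sort(x)
  n <- length(s)
  best <- Inf; bj <- 1
  for (j in 1:(n - 1)) {
    lo <- s[1:j]; hi <- s[(j + 1):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) { best <- w; bj <- j }
  }
  list(wcss = best, split = bj, boundary_value = s[bj],
       means = c(mean(s[1:bj]), mean(s[(bj + 1):n])))
}
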