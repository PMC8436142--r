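# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A 15-minute synthetic night without artifacts: the workhorse for the
# detection tests (bursts only in N2, ~13 N2 minutes).
small_night <- function() {
  fixture("small_night", function() {
    sim <- synth_generate(synth_config(duration_min = 15, seed = 3,
                                       artifact_rate_per_hour = 0))
    sim$spec <- compute_spectrogram(sim$recording)
    sim
  })
}

# Build a spectrogram object directly from a dB image (freq x time), for
# constructed-column tests of the peak machinery.
spec_from_db <- function(db, freqs, times, step_s = NULL) {
  if (is.null(step_s)) step_s <- times[2] - times[1]
  structure(list(times = times, freqs = freqs, power = 10^(db / 10),
                 params = spectrogram_params(step_s = step_s),
                 fs = 100),
            class = "tfs_spectrogram")
}

# A tiny event table shorthand
ev <- function(starts, ends, method = "x", subject = "s1", night = 1L, ...) {
  event_table(start_s = starts, end_s = ends, method = method,
              subject = subject, night = night, ...)
}
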