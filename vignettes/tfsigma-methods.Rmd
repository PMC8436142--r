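---
title: "Detecting sigma-range time-frequency peaks in sleep EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfsigma methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sleep spindles — transient 10–16 Hz oscillatory bursts during NREM sleep —
are traditionally identified by eye on the EEG time trace, or by automated
detectors tuned to reproduce that hand-scoring. Because the sleep EEG is a
superposition of activity across many frequencies, a modest sigma-band
burst is easily hidden under higher-amplitude slow activity, so
waveform-based scoring systematically favours the largest events. Viewed
in the time-frequency domain, every transient oscillation appears as a
circumscribed local maximum of the spectrogram; detecting those maxima
directly gives an event class (sigma-range time-frequency peaks, "TF sigma
peaks") that contains the traditional spindles as its high-prominence
subset. This package implements that time-frequency detector, a reference
wavelet spindle detector for comparison, and the statistical machinery to
compare the two event populations.

## The detection model

**Multitaper spectrogram.** Power is estimated in 1 s windows stepped by
0.05 s, with time-half-bandwidth product 2 and 3 Slepian (DPSS) tapers, a
minimum of 1024 DFT points and constant (mean) detrending per window. The
spectral resolution is $2\,TW/T = 4$ Hz. Windows are timestamped at their
centers; scaling is one-sided PSD (division by $f_s$, factor 2 off
DC/Nyquist), so absolute values are in µV²/Hz. These parameters are fixed
by the method being implemented; `spectrogram_params()` exposes them.

**Two-step prominence extraction.** For each time column the power
spectrum (in dB) is searched for local maxima; the topographic prominence
of each maximum is its height above the higher of its two flanking minima,
where each flanking minimum is the lowest value between the peak and the
nearest strictly higher sample. The largest-prominence peak with apex
inside the search band (the 10–16 Hz sigma range widened by 1 Hz on each
side, to accommodate the 4 Hz main lobe) defines the column's prominence
value, central frequency, and spectral half-prominence width. One
deliberate choice: local maxima and prominence bases are computed over the
*full* spectrum, with only the winning apex confined to the search band.
Clipping the bases at the band edges would make the left base a single
noisy band-edge bin whenever the sigma lobe fills most of the band, which
empirically injects several dB of column-to-column jitter into the trace
and fragments temporal peaks. The temporal pass then finds local maxima of
the prominence trace; each becomes one TF peak with temporal bounds at the
half-prominence crossings (linear interpolation), prominence equal to the
trace value at the apex, and frequency/bandwidth read off the frequency
step at the apex. Duration and bandwidth are therefore both full widths at
half prominence — the standard prominence-based width, and consistent with
the 2 Hz ("half the spectral resolution") resolvability argument used to
filter candidates. Ties anywhere break to the earliest time, then the
lowest frequency, making the whole chain deterministic.

**Unsupervised event/noise separation.** Candidate peaks shorter than
0.3 s or narrower than 2 Hz are excluded; the natural log of the remaining
prominences (prominence is approximately log-normal) is split by exact
two-class k-means. In one dimension the optimal k-means partition is a
contiguous split of the sorted values, so the within-class sum of squares
is minimized exactly by enumeration — identical objective to Lloyd
iterations, but with no random initialization and hence bit-reproducible
results. The base of the logarithm is immaterial: any fixed base rescales
all values affinely and cannot change the optimal contiguous split.
The higher-mean class is labelled "event"; events with central frequency
outside 10–16 Hz are finally discarded.

**Wavelet spindle detector.** The comparator transforms the trace with a
bank of complex Morlet wavelets spanning 10–16 Hz, computes the square of
the real part of the squared coefficient per sample, averages across
scales, and smooths with a 100 ms moving average. The detection threshold
is 4.5 times the mean of this statistic over artifact-free N2 sleep;
supra-threshold runs of 0.3–3 s become events (longer runs truncated at
3 s), and an event starting less than 1 s after the previous onset is
discarded. The exact eight parameters of the original MATLAB wavelet are
not published; this implementation uses integer center frequencies
10–16 Hz with 7 cycles each, which reproduces the stated scale coverage;
numerical parity with the original code is explicitly out of reach and the
bank is exposed via `wavelet_params()` for sensitivity analysis. The
fourth-power statistic makes the detector steeply amplitude-selective
(scaling the signal by $c$ scales the statistic by $c^4$), which is what
lets a high threshold encode the "rarity assumption" on spindles.

## Artifact rejection

Two high-pass passes (35 Hz for high-frequency noise, 2 Hz for broadband
noise; 8th-order Butterworth applied forward–backward in second-order
sections, so artifact boundaries are not phase-shifted) are each followed
by: analytic-signal amplitude (FFT Hilbert transform), natural log with a
machine-epsilon floor, 2 s moving average, and least-squares cubic-spline
detrending with 300 uniformly spaced interior knots. Samples more than 4
SD from the mean are flagged iteratively, with mean/SD recomputed over
unflagged samples only, until convergence (cap 50 iterations; the flagged
set only grows, so termination is guaranteed). The final mask is the union
of the two passes. When the sampling rate cannot support the 35 Hz cutoff
(e.g. 50 Hz recordings), the high-frequency pass is skipped with a warning
rather than silently re-parameterized.

## Comparison statistics

Event matching is deliberately asymmetric, following the event-based
true-positive semantics of reference-anchored evaluation: every detection
overlapping at least one reference event is a TP (several detections on
one reference each count; one detection spanning several references counts
once), detections with no overlap are FPs, and reference events with no
overlapping detection are FNs; recall is the fraction of reference events
overlapped. Overlap percentage is intersection-over-union of covered
sample points on the recording's sample grid, averaged over overlapping
TP pairs. With zero detections precision is reported as NaN and F1 as 0,
which keeps threshold scans total. Property comparisons use paired t-tests
on per-subject medians (medians because all four properties are
heavy-tailed), and bin-wise rate tests use a modified z-score
$(X - \mathrm{median})/\mathrm{SD}$ anchored to one method's events, seven
bins with edges $(-\infty,-2.5,-1.5,-0.5,0.5,1.5,2.5,\infty)$, and
two-sided Wilcoxon signed-rank tests across subjects. Night-to-night
stability uses Pearson correlations, robust regression (bisquare IRLS,
tuning constant 4.685, the conventional 95%-efficiency value; slope CI
from the robust fit's coefficient covariance), and a one-sided permutation
test on the difference of correlations in which each subject's z-scored
(night 1, night 2) pair is randomly swapped between methods.

## The synthetic world

`synth_generate()` produces the test bed every detector is validated on:
1/f (pink) background noise (default SD 15 µV), a 0.8 Hz slow component
(40 µV) during N2/N3, sigma bursts placed by a Poisson process at
10/min during N2, and 0.5 s broadband 500 µV artifacts at 2/h. Bursts are
Gaussian-windowed sinusoids with frequency ~ N(13, 1) truncated to
10–16 Hz and log-normal durations (median 0.8 s, truncated to 0.3–3 s).
Amplitudes follow a two-component model — envelope peaks of 5 µV and 15 µV
with one third of bursts in the high component — so that the high subset
mimics traditional spindles while the full set mimics the broader TF peak
class; a continuous log-normal mode is available for distribution-shape
work. The stated ground-truth duration is the full width at half maximum
of the envelope ($\sigma = \mathrm{duration}/2.355$). This convention was
chosen once, on first principles: FWHM is the standard width of a
Gaussian, and it is the same convention as the detector's half-prominence
widths, so generator truth and measured durations are commensurable.
Bursts are rejected against overlap (0.5 s minimum gap) to keep matching
unambiguous.

What the generator does *not* emulate: real EEG's non-Gaussian background,
spindle frequency chirp, slow-oscillation phase coupling, REM phenomenology
and multichannel structure. A green test on this world therefore
establishes algorithmic correctness and internal consistency, not clinical
performance.

### Known limitations of the stated world

Two behaviours of the defaults deserve explicit statement.

First, a 5 µV burst against 15 µV pink noise is a weak event: the sigma
band inherits roughly 1.5–2 µV²/Hz of background density, so the burst
raises the local spectrum by only ~3–4 dB, while the 3-taper estimator's
own fluctuation is ~2.7 dB. Low-component bursts are therefore genuinely
marginal — many produce no well-formed candidate at all, and those that do
overlap the noise-peak prominence distribution. Event-level recall against
the complete ground truth consequently saturates well below 0.9 at these
settings for any detector operating on the spectrogram, and the
recall/precision acceptance thresholds for the default world are reported
red rather than met by retuning amplitudes after the fact. The
high-amplitude component is recovered essentially completely by both
detectors.

Second, two-class k-means has no notion of "no events": on pure noise it
still splits the unimodal prominence distribution and labels the upper
part as events (roughly half of the — already heavily filtered — candidate
pool). This is a property of the method, not of the implementation; it is
harmless on data that actually contain events, which is the intended
regime.

## Numerical choices

Butterworth filters are designed from the analog prototype with bilinear
pre-warping, section by section; filtering always runs in second-order
sections and zero-phase (forward–backward with odd-reflection padding of
up to 1000 samples). The design was verified against an independent
implementation to machine precision during development and is covered by
passband/stopband tests. The DPSS tapers come from the symmetric
tridiagonal eigenproblem, unit-normalized with the conventional polarity.
Spline detrending fits the basis on a decimated subgrid (at least 30
points per basis function) and evaluates in chunks, which keeps the
artifact detector linear-time in practice. dB is always $10\log_{10}$;
power is floored at $10^{-300}$ before logging. Half-prominence crossings
interpolate linearly and are clipped at the prominence bases. EDF output
scales to the full 16-bit range of each signal, so round-trips are exact
to one quantization step.

## Design decisions that were genuinely open

- *Cluster scope:* candidates from the whole artifact-free record (all
  stages) are clustered per subject, and stage filtering is applied
  afterwards during event selection. Clustering N2-only would couple the
  detector to staging quality; the chosen order matches the per-subject
  clustering description and keeps the detector stage-agnostic.
- *Truncation vs rejection* of supra-threshold runs longer than 3 s: runs
  are truncated to their first 3 s. The alternatives are stated to have
  negligible impact; truncation preserves the event onset, which the 1 s
  separation rule operates on.
- *Permutation unit:* subject-level swaps of each subject's z-scored
  (night 1, night 2) rate pair between methods, preserving the within-
  subject pairing while exchanging method labels, with a one-sided
  p-value (is the first method's correlation larger).
- *Precision with zero detections* is NaN (F1 then 0) so that threshold
  grids remain total functions of the scalar.
- *50 Hz recordings:* the 35 Hz artifact pass cannot run below a 70 Hz
  sampling rate; it is skipped with a warning instead of guessing a
  different cutoff.
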