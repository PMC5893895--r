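---
title: "Recurrence, beats and the Devil's staircase: methods behind recurtone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrence, beats and the Devil's staircase: methods behind recurtone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(recurtone)
```

## The problem

When two pure tones sound together, listeners judge the mixture consonant
when the frequency ratio f2/f1 is a small-integer rational (2/1, 3/2,
4/3, ...) and dissonant elsewhere. `recurtone` implements a purely
signal-level account of this ranking: the *recurrence* of the joint
waveform — how often the trajectory of its delay-embedded state space
revisits already-visited states — peaks exactly at the just-intonation
rationals, and the peak heights fall in the classical consonance order.
No frequency estimation, spectral model or perceptual parameter enters the
computation.

The package covers the full chain: stimulus synthesis, a from-scratch RQA
engine, a sliding-window scan that maps percent recurrence onto the
interval-ratio axis, peak detection and rational matching, beat-rate
measurement, and the connection to mode locking in the sine circle map.

## Stimuli

`pure_tone()`, `mistuned_interval()` and `glissando_mix()` synthesize every
signal the analysis needs. The reference stimulus is a linear glissando
from 360 to 840 Hz mixed with a fixed 400 Hz tone, 6 s at 8000 samples/s,
so the instantaneous interval ratio sweeps 0.9 to 2.1 and crosses every
interval of the octave. Choices the source material leaves open, fixed
here once:

* **Stereo-to-mono mixing** is the per-sample mean. Any fixed linear gain
  would do: percent recurrence under a *relative* radius policy is
  scale-invariant.
* **Initial phases** default to zero for all tones, and the two channels
  have equal amplitude (the published waveform figures show symmetric
  interference).
* **Chirp phase** is the continuous integral of the linear frequency law,
  `phi(t) = 2*pi*(f_start*t + (f_end - f_start)*t^2/(2*duration))`, so the
  sweep has no phase discontinuities. The instantaneous frequency
  (finite-difference of unwrapped analytic phase) matches the linear
  target to well under 0.1 Hz away from the Hilbert edge transients.
* **Time indexing** is 0-based: sample n sits at t = n/rate.

Signals round-trip through two plain formats: one-sample-per-line text
with a `# rate=` header (exact), and RIFF 16-bit PCM mono WAV (exact up to
the 2^-15 quantization step).

## Recurrence quantification

`embed_series(x, m, L)` builds the delay embedding (epoch i is
`(x[i], x[i+L], ..., x[i+(m-1)L])`), `epoch_distances()` the Euclidean
distance matrix, and `recurrence(D, r)` the recurrence plot and the single
descriptor used throughout: percent recurrence, `100 * #{d_ij < r, i<j} /
(N(N-1)/2)`. Conventions worth stating:

* Recurrence is **strict** (`d < r`); ties at exactly the radius are
  non-recurrent.
* The denominator counts unordered epoch pairs of the *embedded* series.
* Four radius policies are provided (`select_radius()`): fraction of the
  mean distance (the field's "5–10% of the mean" rule), a Gaussian
  percentile (mean − z·SD, population SD), an empirical percentile
  (interpolated quantile), and an absolute radius. On the classic
  10-value worked series, the Gaussian 5% policy lands between the second
  and third smallest distances, reproducing the textbook count of two
  recurrences in 28 pairs (7.1%).

`ami_first_minimum()` selects the embedding lag at the first local minimum
of histogram mutual information (16 equal-width bins). Two guards make the
estimator honest: a series whose lag-1 MI does not exceed twice the
plug-in bias `(bins-1)^2/(2N)` is declared structureless (white noise
would otherwise yield spurious local minima at the noise level), and a
warning is raised when `N < bins^2`. A caveat found while testing: a
noiseless sinusoid sampled at an exact integer number of points per cycle
occupies only that many joint states, so its binned MI curve is
degenerate-flat; any realistic (noisy or incommensurately sampled) series
shows the expected quarter-period minimum.

## The sliding scan (RQE)

`rqe()` scans the glissando with 480-sample windows shifted by 48 samples,
embedding dimension 5, lag 3 — giving 991 windows over the 6-s sweep, each
mapped to the mean interval ratio of its samples. The radius is
recomputed **per window** as 10% of that window's mean epoch distance.
This is the central numerical choice of the package, and it is what makes
the profile meaningful on a stimulus whose amplitude texture changes along
the sweep: a relative radius makes each window's percent recurrence
invariant to local amplitude, so peaks reflect the *temporal organization*
(near-periodicity at rational ratios) rather than loudness.

The absolute recurrence magnitudes of the original windowed analyses are
not recoverable — they depend on a radius convention buried in a
proprietary tool — so magnitudes here are treated as rank-order
information. For anchoring, `calibrate_radius()` returns the absolute
global radius that saturates the unison window at exactly 100%.

Under the defaults the peak structure is: unison ~4.8%, octave ~4.6%,
fifth ~2.2%, fourth and major sixth ~1.5%, major third ~1.2%, with weaker
rationals below. The heights scale roughly with 1/q for a ratio p/q in
lowest terms — the waveform at ratio p/q is periodic with fundamental
f1/q, so a fraction ~1/(20q) of epoch pairs are (near-)exact repeats —
which is exactly why recurrence ranks with consonance. Intervals beyond
the major third fall under the default peak prominence (1 percent-unit);
the package reports rank statistics over the matched set rather than
forcing detections.

## Peaks, rationals, Frova's index

`detect_peaks()` finds strict local maxima, computes topographic
prominence, enforces a minimum ratio separation of 0.01 (ties keep the
lower ratio), and matches each peak to the nearest reduced fraction with
denominator ≤ 11 (`match_rational()`, accepted within 0.005).
`rank_consonance()` compares the recurrence ordering of matched reference
intervals with the classical order U > P8 > P5 > P4 > M6 > M3 > m3 > m6 >
m7 > M7 (Spearman rho), and `frova_correlation()` regresses peak
recurrence on the simplicity index `(m+n)/(m*n)` of the matched rationals.
On the default pipeline the six matched reference intervals come out in
exactly the reference order (rho = 1) and the Frova correlation is
r ≈ 0.98.

The 31-row interval catalog is reproduced as published, including one
internal inconsistency: the row at ratio 1.8567 is labeled 15/8 although
15/8 = 1.875 matches only the 1.8747 row; it carries a `caveat` flag.

## Beats

`envelope_beat_rate()` extracts the amplitude envelope (magnitude of the
analytic signal), low-passes it at 50 Hz — above every beat rate of
interest, below the separation of distinct tones — and counts envelope
maxima; mixtures like 400 + 403 Hz give 3 beats/s. Wide mistuned
intervals have a flat envelope and are flagged rather than forced.

`pattern_beat_rate()` measures second-order beats: the rate at which the
*shape* of the waveform recurs. A probe window of 20 carrier periods is
correlated against the delayed signal over lags 0.05–1.5 s; the first lag
cluster whose (sub-sample-refined) correlation reaches 0.9995 marks the
pattern recurrence time T*, and the rate is 1/T*. Numerical choices that
matter, with their reasons:

* **Sinc upsampling (×8)**: at 8000 samples/s the true T* is generally
  not an integer number of samples; without upsampling, carrier
  misalignment alone caps the attainable correlation below any usable
  threshold. Band-limited signals make FFT upsampling exact.
* **Probe length 20 periods**: over a window of only a couple of carrier
  periods the two tones are far from orthogonal and Pearson correlation
  cannot distinguish a true pattern recurrence from a near-alignment of
  either tone alone.
* **Threshold 0.9995**: true recurrences (both tones jointly aligned)
  reach 1 − r ≲ 1e-5 after parabolic peak refinement; the best
  "compromise" lags stall at 1 − r ≳ 5e-4. The threshold separates the
  two regimes with an order of magnitude on either side.
* **Tuned detection**: a perfectly tuned interval is exactly periodic at
  its gcd fundamental, so qualifying lags form a dense comb across the
  whole search range rather than isolated clusters; the period is then
  read off the comb spacing and flagged `tuned`.

For a mixture mistuned by ε from p/q the measured rate is q·ε within 5%
(tested for octave, fifth, fourth at several ε), reproducing the classical
ε / 2ε / 3ε hierarchy.

## The circle map and the staircase

`circle_map_orbit()` iterates
`theta[n+1] = theta[n] + omega + (k/2π)·sin(2π·theta[n])` on the lift;
`winding_number()` measures the dressed winding number w, and
`devils_staircase()` computes w(Ω) on a grid (all grid points iterated
simultaneously). At k = 0, w = Ω to machine precision; at the critical
coupling k = 1 the staircase is non-decreasing with a plateau at every
rational.

Finite-time estimation at k = 1 has a subtlety worth recording: the map's
derivative vanishes once per cycle, so locked orbits are approached
*algebraically*, and the whole-window winding estimate carries a transient
phase slip of order 0.1/n_iter that does not shrink with longer burn-in.
Consequences built into the package:

* Staircase monotonicity holds up to a slack of ~2e-5 at the default
  10^4 iterations (the slip bound), not exactly.
* `plateau_width()` classifies plateau membership from the rotation of the
  orbit's final 2000 iterations (forced to a whole number of q-cycles),
  where the residual slip is ~0.1·tail/n_iter², and finds both edges by
  monotone bisection of w(Ω). Seeding the search at Ω = p/q would fail at
  k = 1: the tongues bend, and Ω = 1/3 itself locks to 8/25.

Measured at k = 1: width(1/2) ≈ 0.074 > width(1/3) ≈ 0.031 >
width(1/4) ≈ 0.016, symmetric under p/q ↔ (q−p)/q, with all interior
plateaus of denominator ≤ 8 summing to ≈ 0.26 < 1.

`cumulative_recurrence()` turns the RQE profile into an empirical
staircase (running sum of percent recurrence along the ratio axis,
normalized to [0, 1]); `compare_staircases()` maps the in-octave ratio
axis onto [0, 1], resamples both curves on a common grid and reports the
sup-norm difference and Pearson correlation — and, because the published
axis convention for the empirical curve is ambiguous, also the correlation
with the empirical axes transposed. On the default pipeline the empirical
curve correlates with the k = 1 staircase at r ≈ 0.98.

## What the synthetic world does and does not establish

Everything analyzed here is synthesized: deterministic, noise-free,
equal-amplitude sine mixtures at exactly the stated frequencies. That is
faithful to the stimulus-generation procedure being emulated, and it makes
every pipeline number reproducible bit-for-bit. It also bounds what a
green test shows: robustness to amplitude imbalance between tones,
background noise, harmonic-rich (complex) tones, or room acoustics is
*not* tested — the dissonance-curve literature for complex tones is a
different computation and explicitly out of scope, as is any perceptual
or neural modeling. The beat-rate thresholds (envelope modulation depth
0.1, correlation 0.9995) were set from the analysis of the clean two-tone
case and would need re-examination for noisy recordings.

## Reproducing the full analysis

```{r}
res <- run_reproduction(pipeline_config(), out_dir = "recurtone_out")
res$ranking   # U > P8 > P5 > P4 > M6 > M3, rho = 1
res$frova     # Pearson r ~ 0.98
res$comparison
```

`scripts/acceptance.R` recomputes the headline quantities (worked-example
distances and the two beat rates) from scratch and writes them as JSON;
the testthat suite asserts every criterion above at its stated tolerance.
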