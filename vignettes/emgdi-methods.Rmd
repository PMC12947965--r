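---
title: "Detecting inspiratory EMGdi activity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inspiratory EMGdi activity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science behind each
stage: the signal model, the tunable parameters and their defaults, the
numerical choices made where several readings were defensible, and what
the synthetic validation does and does not demonstrate about real
recordings.

## Signal model and assumptions

Surface EMGdi is modelled as a zero-mean stochastic process whose
instantaneous power rises during inspiration, superimposed with three
deterministic contaminants: the ECG (by far the largest), mains
interference, and slow baseline drift. The pipeline assumes

* a single channel sampled at a known rate (nominally 500 Hz with an
  analogue 0–200 Hz acquisition band);
* cardiac activity that is repetitive in shape from beat to beat, so it
  can be localized by a QRS detector and either excised, truncated in
  the wavelet domain, or cancelled against a template;
* inspiratory bursts lasting longer than 200 ms and separated by basal
  expiratory phases in which the envelope returns near a stable mode.

## Preprocessing

**Band-pass.** A 4th-order zero-phase Butterworth band-pass at 5–200 Hz
removes drift and out-of-band noise. It is realized as a cascade of an
order-4 high-pass and an order-4 low-pass, each applied forward and
backward over an odd-reflection-padded signal. A single transfer-function
band-pass with a normalized lower edge of 5/250 is numerically fragile
(the pole cluster near `z = 1` makes `filtfilt` leak DC); the cascade is
exact to the analytic squared-magnitude Butterworth response to within
1 % in the passband and is what the test suite checks against. When the
requested upper edge is not realizable the filter clips it to
0.95 × Nyquist with a warning.

**Mains notch.** Each mains harmonic is attenuated by a zero-phase IIR
biquad notch whose quality factor starts at `Q = 35` and is scaled by
×1.25 steps (at most 20 iterations) until the residual power in a
±1 Hz band at the harmonic lies within 10 % of the mean power in two
±1 Hz sidebands centred 3 Hz away. If a Q step no longer changes the
ratio the residual has reached the local noise floor and the iteration
stops; this prevents endless narrowing on records that contain no line
component at all.

**QRS detection.** A Pan–Tompkins-style detector runs on the 5–40 Hz
zero-phase band (where the QRS dominates the EMG): derivative, squaring,
150 ms moving-window integration, adaptive dual thresholds with a 200 ms
refractory period and RR-gap search-back, with classic published
constants (threshold learning rates 1/8, search-back trigger at
1.66 × mean RR). Detections are refined to the local extremum of the
5–40 Hz signal within ±40 ms. On records without cardiac activity the
detector still returns whatever crosses its thresholds, flagged
low-confidence (peak prominence < 3 × the median integrated level or RR
coefficient of variation ≥ 0.5); downstream stages must and do tolerate
such trains.

**ECG exclusion windows.** Samples from 135 ms before to 365 ms after
each R-peak are excluded when estimating signal quality. Windows are
closed sample intervals `[r − round(0.135 fs), r + round(0.365 fs)]`
(251 samples at 500 Hz) and overlapping windows merge by union.

**Signal quality (I2BSNR).** Per consecutive 30 s epoch, the
inspiratory-to-basal SNR is `20 log10` of the RMS of samples inside
detected inspiratory intervals (outside exclusion windows) over the RMS
of samples outside both. Epochs with under 250 ms of either class are
flagged missing and, where the bias correction needs a value, filled by
carrying the last valid epoch forward (and the first valid one
backward). I2BSNR of 1.97–15 dB is typical of overnight clinical
recordings; the simulation grid below covers 1.58–20 dB.

## ECG suppression

**Wavelet denoising.** Four-level Daubechies-4 decomposition; the
level-4 approximation — everything below `fs/32` = 15.625 Hz at 500 Hz,
dominated by P/T waves — is discarded, and detail coefficients inside
per-level windows around each R-peak are truncated at `K = 5` times a
robust scale. Because no wavelet package ships with the targeted R
stack, the periodized orthogonal filter bank is implemented in the
package and validated by perfect-reconstruction, energy-conservation and
band-splitting tests, with the filter taps checked against an
independent wavelet library. Open details were resolved as follows: the
threshold window grows linearly from `Lb` = 200 ms at level 1 to `Ub` =
300 ms at level 4 (deeper levels are coarser, so cardiac energy smears
wider); the robust scale is `1.4826 × median |d|` over coefficients
*outside* all R-windows at that level; truncation applies inside the
windows only — unless no R-peaks are available, in which case a global
truncation is applied under a warning.

**Gating.** A 2nd-order zero-phase 45 Hz high-pass first strips P/T-wave
energy so that only a 130 ms window per beat needs replacement.
Replacement is a straight line joining the RMS of the 65 ms windows
immediately before and after the gated segment. The replacement is
inserted as that nonnegative magnitude trace itself (not sign-randomized
noise): its consumers are amplitude/complexity envelopes that only see
magnitude, and the endpoints are defined by RMS levels, not by samples.

**Adaptive cancellation.** A beat template is the average of the
`[−200, +400]` ms segments around each R-peak after dropping the 25 %
with the highest energy (those most likely to carry inspiratory EMG);
tiling it at every R-peak (later copies overwrite overlaps — it is a
beat train, not a convolution) gives a reference correlated with the ECG
but not with the EMG. An LMS filter with taps spanning 0.4 s adapts the
reference onto the record; the step size is normalized by the reference
power and tuned on a logarithmic grid plus bisection (at most 12
criterion evaluations) until the cancellation energy matches the
reference energy within 5 %. Divergence (non-finite error or residual
energy above twice the input) halves the step and restarts, at most 5
times; if the criterion is unreachable — e.g. the reference is
essentially uncorrelated with the record — the most energy-consistent
stable step is used under a warning, which leaves the record nearly
unchanged, the correct behaviour in that case.

**Adaptive + gating.** Gating applied to the adaptively filtered signal
with the 45 Hz high-pass disabled (the adaptive stage has already
removed the low-frequency cardiac components); it exists to flatten the
residual high-frequency QRS spikes the LMS stage can leave on some
beats.

## Envelopes

Stage e1 is either a 250 ms centred moving RMS or fixed sample entropy
over the same window with embedding dimension `m = 1` and tolerance
`r = 0.4 ×` the standard deviation of the whole preprocessed record.
Keeping `r` fixed per record (rather than per window) is the property
that makes fSE an *amplitude-sensitive* envelope: windows whose spread
is large relative to `r` produce few template matches and high entropy.
A deterministic repetitive ECG changes the match counts far less than it
changes the RMS, which is why fSE can run on unfiltered or adaptively
filtered records — but not on gated or wavelet-truncated ones, whose
artificially regularized QRS segments punch spurious notches into the
entropy trace; those combinations are rejected with an explanatory
error.

Windows where `-ln(A/B)` is undefined get the ceiling `ln(B(B−1))` when
`B ≥ 2` (the largest value a window with `B` template matches could
produce, preserving the "more random ⇒ larger" ordering), else they
repeat the nearest defined value. All moving windows are centred — odd
sample counts split evenly, even counts take the extra sample on the
left — and shrink at the record edges, so envelope sample *k* is always
centred on signal sample *k*.

Stage e2 smooths e1 with a 300 ms moving average, comparable to the QRS
duration, spreading residual cardiac spikes below detection amplitude.
Stage e3 is `10^ê2` with ê2 the per-record Min–Max normalization of e2.
Exponentiating the raw envelope would overflow and make every threshold
unit-dependent; normalizing first bounds e3 in `[1, 10]`, makes it
unit-free, and preserves monotonicity while strongly expanding
high-amplitude excursions relative to cardiac ripple.

## Cycle detection and onset/offset localization

A slow (3 s) moving average of the envelope tracks the baseline; a fast
(1 s) one tracks respiration while averaging out cardiac-rate
variation. Each maximal run with fast > slow, bounded by an upward and
the following downward crossing, is a candidate cycle annotated at the
run's temporal midpoint ("midpoint between crossings" is read as the
midpoint of the fast-above-slow run; runs touching the record edges have
no bounding crossing and are dropped). Cycles shorter than 200 ms, or
whose mean envelope is less than 10 % above the mean over flanking
windows of 20 % of the cycle duration, are rejected. The amplitude
filter runs on the provisional moving-average bounds *before*
localization, matching the order in which the criteria apply.

Onset and offset thresholds are the mode — Gaussian-kernel density
estimate, Silverman's bandwidth, argmax on a 512-point grid — of the
envelope between the current marker and the previous (next) marker;
record edges substitute for missing neighbours. From the marker the scan
moves outward until the envelope first dips to or below the threshold;
the mark is the last sample above it. Scans stop at the adjacent marker
or record edge (preventing runaway on drifting baselines), and the onset
is additionally bounded by the previously accepted offset so accepted
cycles can never overlap. A constant segment makes the KDE degenerate;
the threshold is then set just above the segment value, which collapses
the cycle and rejects it by the 200 ms rule. Finally, the Shannon
entropy of the envelope histogram within the cycle — 32 equal-width bins
over the pooled range of the cycle and its two flanking phases, with
`0·log 0 = 0` — must be at least that of both flanking phases; genuine
bursts sweep a wide amplitude range, whereas residual artefacts tend to
be narrow and peaked.

## The synthetic generator

The generator emulates the validation protocol used to characterize the
detector's timing bias: Gaussian white noise whose standard deviation
follows `basal_sd · (1 + α · e(t))`, with `e(t) = 1 − 4(t − 1)²` on
`0.5 ≤ t ≤ 1.5` s of each cycle and zero elsewhere. The gain α is
calibrated in closed form — using the support means `∫e = 2/3` and
`∫e² = 8/15` — so that the *segment RMS ratio* between the inspiratory
support and the basal remainder equals the requested `rms_ratio`
exactly; this is the calibration under which a ratio of 10 corresponds
to an I2BSNR of 20 dB and 1.2 to 1.58 dB, which the tests verify on the
generated samples. Defaults chosen where the protocol leaves freedom:
`cycle_period = 2` s (inspiration 0.5–1.5 s, symmetric basal padding, a
physiologically plausible 30 breaths/min envelope), `basal_sd = 1`
(the detectors are scale-free), noise drawn in one stream per record.
Optional contaminants are a sum-of-Gaussians P-QRS-T train (R-wave
scaled to a multiple of the record's robust basal RMS,
`median|x|/0.6745`, with 2 % RR jitter) and a 50 Hz sinusoid with
optional harmonics. The ECG injection is purely additive and returns its
own R-peak truth, closing the loop for the QRS detector and the
suppression methods.

What the generator does *not* emulate: the coloured spectrum and
amplitude distribution of real interference-pattern EMG, motion and
electrode-contact artefacts, baseline wander, beat-to-beat QRS
morphology variation, breath-to-breath variability of timing and
amplitude, and ventilator-driven pressurization artefacts. Passing the
synthetic suites therefore demonstrates the internal correctness and
calibration of the pipeline — not clinical-grade performance, which can
only be established against expert annotations of real recordings.

## Timing-bias characterization and correction

Envelope smoothing biases every threshold detector: onsets are detected
early and offsets late, by amounts that shrink as signal quality rises.
`run_bias_simulation()` measures this on the generator across an I2BSNR
grid — detections are matched to truth by interval overlap (maximum
one-to-one matching) and the mean error ME and SD of `detected − true`
recorded per level. The package's reduced study conditions are 9 levels
spanning 1.58–20 dB with 200 cycles per level; at this size the
per-level ME estimates are stable to a few milliseconds and the full
sweep runs in seconds, and `scripts/acceptance.R` reproduces it from
scratch.

The mean error is fitted with the double exponential
`c(x) = a e^{bx} + c e^{dx}` by Levenberg–Marquardt least squares,
multi-started over the sign patterns of `(a, c)` and decay-rate
initializations `{−0.5, −0.05, −0.001, −0.3}`, keeping the best-RMSE
fit; if every start fails, a single exponential is fitted under a
warning. Only the mean error is corrected; the SD curves are reported
but not corrected, and the tests verify that correction changes
per-level dispersion by well under 10 %. The sign convention is fixed
everywhere as `error = detected − true`, so the correction *subtracts*
the fitted error. Outside the fitted range the exponentials are not
trusted: evaluations clamp the I2BSNR to the grid endpoints. The
correction applies per 30 s epoch at that epoch's estimated I2BSNR. One
caveat is surfaced as a warning: the exponential family fits RMS-e3
*onset* curves poorly, and corrected onsets from that combination should
be treated with care; the fSE-based envelopes do not share the problem.

## Evaluation conventions

Scorer intervals that overlap (closed intervals, any positive-length
intersection) refer to the same effort. Only uniquely matched pairs form
reliable events — an interval overlapping two counterparts has no unique
match and is excluded along with single-scorer intervals. Within a pair,
onset and offset reliability are judged independently against a strict
150 ms bound, and a reliable marker's reference is the mean of the two
scorers. Detections are matched to reliable-event spans by maximum
one-to-one overlap matching; unmatched detections that touch only
excluded intervals are ignored (no trustworthy reference exists there),
the rest are false positives. Timing metrics use the population SD so
that `RMSE² = MD² + SD²` holds exactly; this convention is asserted in
the tests.

## Known limitations

* The QRS detector is self-referenced (no ECG lead); under very strong
  inspiratory EMG it produces false detections, which the suppression
  methods then treat as beats. Gating and wavelet truncation lose
  genuine EMG inside those windows.
* fSE computation is quadratic in the window length; long records at
  high sampling rates pay for it (the compiled kernel processes roughly
  10 k samples per second at the default 125-sample window).
* The bias correction transfers from simulation to data only insofar as
  the generator's envelope shape matches real inspiratory dynamics;
  abrupt-onset efforts will show smaller true bias than the parabolic
  model predicts.
* File I/O is CSV/JSON only; binary acquisition formats should be
  converted upstream.
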