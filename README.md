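# emgdi

Automatic detection of inspiratory onset and offset in surface diaphragm
electromyography (EMGdi).

## The problem

Surface EMGdi recorded at the costal margin reflects the neural drive to
the diaphragm and is the most direct non-invasive window on *when* a
patient tries to breathe. Timing each inspiratory burst — its onset and
its offset (the return to basal expiratory level, i.e. neural
end-inspiration) — is what makes breath-by-breath analysis of
patient–ventilator asynchrony possible during non-invasive ventilation.
But overnight recordings are long, weak and heavily contaminated by the
ECG, and manual annotation is slow and scorer-dependent. `emgdi`
implements a fully automatic pipeline for this problem, together with a
synthetic-signal generator with exact ground truth so that every stage
can be validated without clinical data.

## What the pipeline does

1. **Preprocessing** — zero-phase Butterworth band-pass (5–200 Hz),
   adaptive zero-phase IIR notch filters at the mains harmonics (the
   notch bandwidth is widened/narrowed until the residual line power
   matches the adjacent sidebands), Pan–Tompkins R-peak detection on the
   5–40 Hz band, and ECG exclusion windows from 135 ms before to 365 ms
   after each R-peak.
2. **ECG suppression** — four alternatives: Daubechies-4 wavelet
   denoising with adaptive coefficient truncation around QRS complexes;
   45 Hz high-pass plus gating (130 ms QRS windows replaced by a line
   joining the flanking 65 ms RMS levels); LMS adaptive cancellation
   driven by a beat template synthesized from the record itself; and
   adaptive cancellation followed by gating.
3. **Envelopes** — moving 250 ms RMS or fixed sample entropy (fSE,
   `m = 1`, tolerance `r = 0.4 × SD` of the whole record) as stage e1;
   a 300 ms moving average as e2; and `e3 = 10^ê2` after per-record
   Min–Max normalization. The fSE envelope responds to the random EMG
   component and largely ignores the repetitive deterministic ECG, so it
   needs no prior ECG removal.
4. **Cycle detection** — crossings of a fast (1 s) and a slow (3 s)
   moving average of the envelope mark candidate cycles at the midpoint
   of each fast-above-slow run; cycles shorter than 200 ms or less than
   10 % above their surroundings are discarded. Onset and offset are the
   last envelope samples above an adaptive threshold, the
   kernel-density-estimated mode of the envelope between adjacent cycle
   markers, and a Shannon-entropy plausibility filter removes bursts
   less irregular than their surroundings.
5. **Signal-quality-driven bias correction** — envelope smoothing makes
   detected onsets systematically early and offsets late. The signal
   quality index

   `I2BSNR = 20 log10(RMS_insp / RMS_basal)` (dB)

   is estimated per 30 s epoch, and a correction
   `c(I2BSNR) = a e^{b·I2BSNR} + c e^{d·I2BSNR}`, fitted to mean timing
   errors measured on simulated records of known truth, is subtracted
   from each detected mark.
6. **Evaluation** — two-scorer reference construction (overlap pairing,
   unique matches only, 150 ms marker tolerance, mean-of-scorers
   reference) and event (TP/FP/FN, sensitivity, precision, F1) and
   timing (MD, SD, RMSE) metrics.

The synthetic generator produces Gaussian-noise EMGdi whose inspiratory
standard deviation is modulated by the parabolic envelope
`e(t) = 1 − 4(t − 1)²` on `0.5 ≤ t ≤ 1.5` s of each cycle, calibrated in
closed form so that the inspiratory-to-basal segment RMS ratio is
exactly the requested value, optionally with a sum-of-Gaussians P-QRS-T
ECG and mains interference superimposed.

## Worked example

Simulate two minutes of contaminated EMGdi, run the fSE-e3 pipeline with
adaptive ECG cancellation, and score the detections against the
generator's ground truth treated as a two-scorer consensus:

```r
library(emgdi)

sim <- simulate_emgdi(simulation_spec(
  n_cycles = 60, rms_ratio = 3, seed = 42,
  ecg = ecg_spec(heart_rate = 70, qrs_amplitude = 6)))
sim$record
#> <emg_record> synthetic EMGdi: 60000 samples @ 500 Hz (120.0 s), units a.u., ecg removal: none

cfg <- pipeline_config(ecg_method = "adaptive", envelope_method = "fse",
                       envelope_stage = "e3", notch_harmonics = 0)
res <- run_pipeline(sim$record, cfg)
nrow(res$accepted)
#> [1] 60

truth <- annotation_set("truth", sim$truth$onset_s, sim$truth$offset_s)
ref <- pair_scorers(truth, truth)
match_detections(res$accepted, ref)
#> <match_report> TP 60  FP 0  FN 0 | Se 1.000  Pr 1.000  F1 1.000
timing_metrics(res$accepted, ref, "onset")
#> <timing_report> n 60 | MD -179.7 ms  SD 102.2 ms  RMSE 206.7 ms
timing_metrics(res$accepted, ref, "offset")
#> <timing_report> n 60 | MD +149.9 ms  SD 99.0 ms  RMSE 179.7 ms
```

All 60 simulated efforts are found (F1 = 1.00). The onset marks lead the
true onsets by about 180 ms on average and the offsets lag by about
150 ms — the systematic envelope bias that the correction stage exists
to remove: fit a model with `run_bias_simulation()` +
`fit_correction()` and pass it to `pipeline_config(correction_model =
...)` (or use `apply_correction()` directly) to subtract it per 30 s
epoch. The estimated signal quality here averages 4.5 dB across epochs
(`res$i2bsnr`).

A command-line front end wrapping the same functions ships in
`inst/cli/emgdi.R` with `simulate`, `detect`, `fit-correction` and
`evaluate` subcommands.

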