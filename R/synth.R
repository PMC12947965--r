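#' Parabolic inspiratory amplitude envelope
#'
#' Dimensionless gain applied to the stochastic EMG component during
#' inspiration. Within each respiratory cycle the gain rises from zero at
#' t = 0.5 s to a maximum of one at t = 1 s and returns to zero at
#' t = 1.5 s following `1 - 4 (t - 1)^2`; it is zero elsewhere, so the
#' envelope is continuous everywhere.
#'
#' @param t Time in seconds, non-negative. If `cycle_period` is given, `t`
#'   is first folded into one cycle with `t %% cycle_period`.
#' @param cycle_period Optional cycle duration in seconds.
#' @return Gain values in `[0, 1]`.
#' @export
inspiratory_envelope <- function(t, cycle_period = NULL) {
  if (any(t < 0)) stop("t must be non-negative")
  if (!is.null(cycle_period)) t <- t %% cycle_period
  ifelse(t >= 0.5 & t <= 1.5, 1 - 4 * (t - 1)^2, 0)
}

#' Specification of a synthetic EMGdi signal
#'
#' Defines the simulation conditions: Gaussian-white-noise EMG whose
#' inspiratory segments are amplitude modulated by
#' [inspiratory_envelope()], at a controllable inspiratory-to-basal RMS
#' ratio, optionally contaminated with a synthetic ECG and mains
#' interference.
#'
#' @param n_cycles Number of respiratory cycles (>= 1).
#' @param rms_ratio Target ratio of inspiratory-segment RMS to
#'   basal-segment RMS (>= 1). A ratio of 10 corresponds to an
#'   inspiratory-to-basal SNR of 20 dB.
#' @param seed Integer seed; identical specs produce bit-identical signals.
#' @param sampling_rate Sampling rate in Hz.
#' @param cycle_period Cycle duration in seconds (>= 2 so the inspiratory
#'   support `[0.5, 1.5]` s fits inside one period).
#' @param basal_sd Standard deviation of the basal (expiratory) noise.
#' @param ecg Optional [ecg_spec()] describing injected cardiac artifact.
#' @param mains_amplitude Amplitude of 50 Hz mains interference as a
#'   fraction of the basal RMS (>= 0).
#' @param mains_harmonics Number of mains harmonics (1 = fundamental only).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cycles, rms_ratio, seed,
                            sampling_rate = 500, cycle_period = 2,
                            basal_sd = 1, ecg = NULL,
                            mains_amplitude = 0, mains_harmonics = 1) {
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (rms_ratio < 1) stop("rms_ratio must be >= 1")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (cycle_period < 2) stop("cycle_period must be >= 2 s")
  if (mains_amplitude < 0) stop("mains_amplitude must be >= 0")
  if (!is.null(ecg) && !inherits(ecg, "ecg_spec")) {
    stop("ecg must be an ecg_spec or NULL")
  }
  structure(
    list(n_cycles = as.integer(n_cycles), rms_ratio = rms_ratio,
         seed = as.integer(seed), sampling_rate = sampling_rate,
         cycle_period = cycle_period, basal_sd = basal_sd, ecg = ecg,
         mains_amplitude = mains_amplitude,
         mains_harmonics = as.integer(mains_harmonics)),
    class = "simulation_spec"
  )
}

#' Specification of a synthetic ECG contaminant
#'
#' A periodic P-QRS-T waveform built from a sum of Gaussians, added to a
#' record so that the ECG-suppression stages can be exercised against a
#' known cardiac truth.
#'
#' @param heart_rate Beats per minute, in `[30, 200]`.
#' @param qrs_amplitude R-wave amplitude as a multiple of the record's
#'   basal EMG RMS (>= 0).
#' @param rr_jitter Fractional standard deviation of beat-to-beat interval
#'   jitter (0 for a strictly periodic train).
#' @return An object of class `ecg_spec`.
#' @export
ecg_spec <- function(heart_rate = 70, qrs_amplitude = 5, rr_jitter = 0.02) {
  if (heart_rate < 30 || heart_rate > 200) {
    stop("heart_rate must lie in [30, 200] bpm")
  }
  if (qrs_amplitude < 0) stop("qrs_amplitude must be >= 0")
  structure(list(heart_rate = heart_rate, qrs_amplitude = qrs_amplitude,
                 rr_jitter = rr_jitter),
            class = "ecg_spec")
}

# Modulation gain alpha such that the RMS over the full inspiratory support
# equals rms_ratio times the basal RMS. With e(t) the parabolic envelope,
# mean(e) = 2/3 and mean(e^2) = 8/15 over the support, so
# mean((1 + alpha e)^2) = 1 + (4/3) alpha + (8/15) alpha^2 = rms_ratio^2.
envelope_gain <- function(rms_ratio) {
  if (rms_ratio == 1) return(0)
  a <- 8 / 15
  b <- 4 / 3
  cc <- 1 - rms_ratio^2
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

#' Simulate a synthetic EMGdi record with known cycle timing
#'
#' Generates zero-mean Gaussian white noise whose instantaneous standard
#' deviation follows `basal_sd * (1 + alpha * e(t))`, where `e(t)` is the
#' parabolic inspiratory envelope and `alpha` is calibrated in closed form
#' so that the realized inspiratory-segment RMS over the `[0.5, 1.5]` s
#' support equals `rms_ratio` times the basal RMS (hence an
#' inspiratory-to-basal SNR of `20 log10(rms_ratio)` dB). Optionally adds
#' mains interference and a synthetic ECG.
#'
#' @param spec A [simulation_spec()].
#' @return A list with elements `record` (an [emg_record()]), `truth` (a
#'   data frame with `cycle_index`, `onset_s`, `offset_s`, `marker_s`), and
#'   `rpeaks` (an [rpeak_train()] of injected R-peaks, or `NULL` when no
#'   ECG was requested).
#' @export
simulate_emgdi <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$n_cycles * spec$cycle_period * fs)
  t <- (seq_len(n) - 1) / fs
  phase <- t %% spec$cycle_period
  gain <- 1 + envelope_gain(spec$rms_ratio) * inspiratory_envelope(phase)
  set.seed(spec$seed)
  x <- stats::rnorm(n) * (spec$basal_sd * gain)
  if (spec$mains_amplitude > 0) {
    for (h in seq_len(spec$mains_harmonics)) {
      x <- x + (spec$mains_amplitude * spec$basal_sd / h) *
        sin(2 * pi * 50 * h * t)
    }
  }
  rec <- emg_record(x, fs, label = "synthetic EMGdi", units = "a.u.")
  k <- seq_len(spec$n_cycles) - 1
  truth <- data.frame(cycle_index = k + 1L,
                      onset_s = k * spec$cycle_period + 0.5,
                      offset_s = k * spec$cycle_period + 1.5,
                      marker_s = k * spec$cycle_period + 1.0)
  rpeaks <- NULL
  if (!is.null(spec$ecg) && spec$ecg$qrs_amplitude > 0) {
    inj <- inject_ecg(rec, spec$ecg, seed = spec$seed + 1L)
    rec <- inj$record
    rpeaks <- inj$rpeaks
  }
  list(record = rec, truth = truth, rpeaks = rpeaks)
}

# Sum-of-Gaussians P-QRS-T beat, R-wave normalized to one. Component
# centers/widths in seconds relative to the R peak.
ecg_beat <- function(t_rel) {
  comp <- rbind(
    c(-0.200, 0.15, 0.025),   # P
    c(-0.025, -0.20, 0.010),  # Q
    c(0.000, 1.00, 0.012),    # R
    c(0.025, -0.25, 0.010),   # S
    c(0.250, 0.30, 0.050)     # T
  )
  y <- numeric(length(t_rel))
  for (i in seq_len(nrow(comp))) {
    y <- y + comp[i, 2] * exp(-0.5 * ((t_rel - comp[i, 1]) / comp[i, 3])^2)
  }
  y
}

#' Inject a synthetic ECG into a record
#'
#' Adds a periodic P-QRS-T waveform at the specified heart rate. The
#' injection is purely additive: subtracting the returned `trace` restores
#' the input exactly. The R-wave amplitude is scaled to a multiple of the
#' record's basal RMS, estimated robustly as `median(|x|) / 0.6745` so that
#' inspiratory bursts do not inflate the reference level.
#'
#' @param record An [emg_record()].
#' @param ecg An [ecg_spec()].
#' @param seed Integer seed for beat-to-beat interval jitter.
#' @return A list with `record` (contaminated), `rpeaks` (an
#'   [rpeak_train()] of true R-peak positions) and `trace` (the injected
#'   waveform).
#' @export
inject_ecg <- function(record, ecg, seed = 1L) {
  stopifnot(inherits(record, "emg_record"), inherits(ecg, "ecg_spec"))
  n <- length(record$samples)
  fs <- record$sampling_rate
  if (ecg$qrs_amplitude == 0) {
    return(list(record = record,
                rpeaks = rpeak_train(integer(0), fs),
                trace = numeric(n)))
  }
  basal_rms <- stats::median(abs(record$samples)) / 0.6745
  if (basal_rms == 0) basal_rms <- 1
  rr <- 60 / ecg$heart_rate
  dur <- n / fs
  set.seed(seed)
  beats <- numeric(0)
  tb <- rr / 2
  while (tb < dur) {
    beats <- c(beats, tb)
    jitter <- if (ecg$rr_jitter > 0) stats::rnorm(1, 0, ecg$rr_jitter * rr) else 0
    tb <- tb + max(0.25, rr + jitter)
  }
  t <- (seq_len(n) - 1) / fs
  trace <- numeric(n)
  half <- 0.45  # beat support in seconds on each side of R
  for (b in beats) {
    lo <- max(1L, floor((b - half) * fs) + 1L)
    hi <- min(n, ceiling((b + half) * fs) + 1L)
    idx <- lo:hi
    trace[idx] <- trace[idx] + ecg_beat(t[idx] - b)
  }
  trace <- trace * (ecg$qrs_amplitude * basal_rms)
  out <- record
  out$samples <- record$samples + trace
  list(record = out,
       rpeaks = rpeak_train(round(beats * fs) + 1L, fs),
       trace = trace)
}
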