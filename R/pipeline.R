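#' Pipeline configuration
#'
#' Composes the stages of the detection pipeline: ECG suppression method,
#' envelope method and stage, detector settings and epoch length for the
#' signal-quality series. Fixed-sample-entropy envelopes are rejected for
#' gating and wavelet sources, whose segment removal/truncation around QRS
#' complexes distorts the random EMG component the entropy measures.
#'
#' @param ecg_method One of `"none"`, `"wavelet"`, `"gating"`,
#'   `"adaptive"`, `"adaptive_gating"`.
#' @param envelope_method `"rms"` or `"fse"`.
#' @param envelope_stage `"e1"`, `"e2"` or `"e3"`.
#' @param detector A [detector_config()].
#' @param epoch_length Epoch length in seconds for the I2BSNR series.
#' @param bandpass_low,bandpass_high Preprocessing band edges in Hz.
#' @param notch_harmonics Number of mains harmonics to notch (0 disables
#'   the notch stage).
#' @param mains_freq Mains fundamental in Hz.
#' @param correction_model Optional `correction_model` applied after
#'   detection.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(ecg_method = c("none", "wavelet", "gating",
                                           "adaptive", "adaptive_gating"),
                            envelope_method = c("rms", "fse"),
                            envelope_stage = c("e3", "e1", "e2"),
                            detector = detector_config(),
                            epoch_length = 30,
                            bandpass_low = 5, bandpass_high = 200,
                            notch_harmonics = 1, mains_freq = 50,
                            correction_model = NULL) {
  ecg_method <- match.arg(ecg_method)
  envelope_method <- match.arg(envelope_method)
  envelope_stage <- match.arg(envelope_stage)
  if (envelope_method == "fse" && ecg_method %in% c("wavelet", "gating")) {
    stop("fixed sample entropy cannot be combined with ", ecg_method,
         " ECG suppression: segment removal/truncation around QRS ",
         "complexes distorts the random EMG component")
  }
  if (epoch_length <= 0) stop("epoch_length must be positive")
  structure(list(ecg_method = ecg_method, envelope_method = envelope_method,
                 envelope_stage = envelope_stage, detector = detector,
                 epoch_length = epoch_length, bandpass_low = bandpass_low,
                 bandpass_high = bandpass_high,
                 notch_harmonics = notch_harmonics, mains_freq = mains_freq,
                 correction_model = correction_model),
            class = "pipeline_config")
}

#' Run the full detection pipeline on a record
#'
#' Band-pass filters and (optionally) notch-filters the record, detects
#' R-peaks, applies the configured ECG-suppression method, computes the
#' configured envelope, detects inspiratory cycles, estimates the
#' per-epoch I2BSNR using the detected cycles and the ECG exclusion mask,
#' and, when a correction model is configured, applies the
#' signal-quality-driven timing correction.
#'
#' @param record A raw [emg_record()].
#' @param config A [pipeline_config()].
#' @return A list with `cycles` (all events with flags), `accepted`
#'   (accepted cycles, corrected when a model was given), `i2bsnr`,
#'   `rpeaks`, `envelope` and `config`.
#' @export
run_pipeline <- function(record, config = pipeline_config()) {
  stopifnot(inherits(record, "emg_record"),
            inherits(config, "pipeline_config"))
  rec <- bandpass(record, low = config$bandpass_low,
                  high = config$bandpass_high)
  if (config$notch_harmonics > 0) {
    rec <- notch_mains(rec, base_freq = config$mains_freq,
                       n_harmonics = config$notch_harmonics)
  }
  rpeaks <- detect_r_peaks(rec)
  proc <- switch(config$ecg_method,
    none = rec,
    wavelet = wavelet_denoise(rec, rpeaks),
    gating = gate(rec, rpeaks),
    adaptive = adaptive_cancel(rec, rpeaks),
    adaptive_gating = adaptive_then_gate(rec, rpeaks))
  env <- compute_envelope(proc, method = config$envelope_method,
                          stage = config$envelope_stage)
  cycles <- detect_cycles(env, config$detector)
  acc <- accepted_cycles(cycles)
  mask <- ecg_exclusion_mask(rpeaks, length(rec$samples))
  i2bsnr <- compute_i2bsnr(rec, acc, mask,
                           epoch_length = config$epoch_length)
  if (!is.null(config$correction_model) && nrow(acc)) {
    acc <- apply_correction(acc, i2bsnr, config$correction_model)
  }
  list(cycles = cycles, accepted = acc, i2bsnr = i2bsnr, rpeaks = rpeaks,
       envelope = env, config = config)
}
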