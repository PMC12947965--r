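#' Construct an envelope object
#'
#' Wraps a precomputed nonnegative trace as an `emg_envelope` so it can be
#' fed to the detector; mostly useful for tests and custom envelopes.
#'
#' @param values Numeric envelope samples.
#' @param sampling_rate Sampling rate in Hz (same as the source signal).
#' @param method `"rms"` or `"fse"`.
#' @param stage `"e1"`, `"e2"` or `"e3"`.
#' @param source_method ECG-suppression provenance tag.
#' @return An `emg_envelope`.
#' @export
emg_envelope <- function(values, sampling_rate, method = "rms",
                         stage = "e1", source_method = "none") {
  if (!all(is.finite(values))) stop("envelope values must be finite")
  new_envelope(as.numeric(values), sampling_rate, method, stage,
               source_method)
}

new_envelope <- function(values, sampling_rate, method, stage, source_method) {
  structure(list(values = values, sampling_rate = sampling_rate,
                 method = method, stage = stage,
                 source_method = source_method),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %s %s (%s source): %d samples @ %g Hz\n",
              x$method, x$stage, x$source_method, length(x$values),
              x$sampling_rate))
  invisible(x)
}

#' Moving RMS envelope (stage e1)
#'
#' Root-mean-square amplitude over a centered moving window (250 ms by
#' default). Envelope sample k is centered on signal sample k; at the
#' record edges the window shrinks to the available samples.
#'
#' @param record An [emg_record()].
#' @param window Window length in seconds.
#' @return An `emg_envelope` with `method = "rms"`, `stage = "e1"`.
#' @export
rms_envelope <- function(record, window = 0.250) {
  stopifnot(inherits(record, "emg_record"))
  if (length(record$samples) == 0L) stop("empty signal")
  fs <- record$sampling_rate
  if (window * fs < 2) stop("window must span at least 2 samples")
  wh <- window_halves(window, fs)
  new_envelope(moving_rms(record$samples, wh$left, wh$right), fs,
               "rms", "e1", record$source_method)
}

#' Fixed-sample-entropy parameters
#'
#' @param m Embedding dimension (default 1).
#' @param r Tolerance; defaults (when `NULL`) to 0.4 x the standard
#'   deviation of the whole preprocessed record, computed once per record
#'   rather than per window -- this fixed tolerance is what makes the
#'   envelope sensitive to the amplitude of random EMG activity but
#'   insensitive to the repetitive deterministic ECG waveform.
#' @param window Moving-window length in seconds.
#' @return An object of class `fse_params`.
#' @export
fse_params <- function(m = 1, r = NULL, window = 0.250) {
  if (m < 1) stop("embedding dimension m must be >= 1")
  if (!is.null(r) && r <= 0) stop("tolerance r must be positive")
  structure(list(m = as.integer(m), r = r, window = window),
            class = "fse_params")
}

#' Fixed-sample-entropy envelope (stage e1)
#'
#' Sample entropy `-ln(A/B)` over a centered moving window, where B counts
#' template pairs of length `m` within the fixed global tolerance `r` and
#' A the pairs still matching at length `m + 1`. Windows where no pair
#' matches at length `m + 1` are substituted with the theoretical ceiling
#' `ln(B (B - 1))`; windows with `B < 2` repeat the nearest defined value.
#' Not offered for gating or wavelet sources: those methods remove or
#' truncate signal segments around QRS complexes, artificially lowering
#' local complexity and producing spurious notches in the entropy trace.
#'
#' @param record An [emg_record()] with `source_method` `"none"` or
#'   `"adaptive"`.
#' @param params An [fse_params()].
#' @return An `emg_envelope` with `method = "fse"`, `stage = "e1"`.
#' @export
fse_envelope <- function(record, params = fse_params()) {
  stopifnot(inherits(record, "emg_record"), inherits(params, "fse_params"))
  if (!record$source_method %in% c("none", "adaptive")) {
    stop("fixed sample entropy is not applicable after ", record$source_method,
         ": segment removal/truncation around QRS complexes distorts the ",
         "random EMG component; use an RMS envelope instead")
  }
  fs <- record$sampling_rate
  x <- record$samples
  r <- if (is.null(params$r)) 0.4 * stats::sd(x) else params$r
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive")
  wh <- window_halves(params$window, fs)
  if (wh$n < 10) stop("window must contain at least 10 samples")
  res <- fse_window_counts(x, wh$left, wh$right, r, params$m)
  v <- res$value
  undef <- is.na(v)
  ceiling_ok <- undef & res$B >= 2L
  v[ceiling_ok] <- log(as.numeric(res$B[ceiling_ok]) *
                         (as.numeric(res$B[ceiling_ok]) - 1))
  # remaining undefined windows: repeat the nearest defined neighbour
  if (anyNA(v)) {
    idx <- which(!is.na(v))
    if (!length(idx)) {
      v[] <- 0
    } else {
      near <- idx[pmax(1L, findInterval(seq_along(v), idx))]
      # findInterval gives the defined index at/left of each position;
      # positions before the first defined value map to the first
      v[is.na(v)] <- v[near[is.na(v)]]
    }
  }
  new_envelope(v, fs, "fse", "e1", record$source_method)
}

#' Moving-average smoothing of an envelope (stage e2)
#'
#' Centered moving mean (300 ms by default), shrinking at the edges. The
#' window is comparable to the QRS duration, so residual cardiac spikes in
#' the stage-1 envelope are spread out rather than detected as events.
#'
#' @param e1 An `emg_envelope` (any stage; typically e1).
#' @param window Window length in seconds.
#' @return An `emg_envelope` with `stage = "e2"` and the method preserved.
#' @export
smooth_envelope <- function(e1, window = 0.300) {
  stopifnot(inherits(e1, "emg_envelope"))
  wh <- window_halves(window, e1$sampling_rate)
  new_envelope(moving_mean(e1$values, wh$left, wh$right), e1$sampling_rate,
               e1$method, "e2", e1$source_method)
}

#' Exponential transformation of an envelope (stage e3)
#'
#' Min-Max normalizes the smoothed envelope to `[0, 1]` per record and
#' raises 10 to that power, yielding values in `[1, 10]`. The
#' transformation is strictly monotone, so it preserves the ordering of
#' envelope values while strongly expanding high-amplitude excursions
#' relative to the low-amplitude ripple left by cardiac activity.
#' Normalizing before exponentiation keeps the result bounded and
#' independent of the amplitude units of the recording.
#'
#' @param e2 An `emg_envelope` (typically stage e2).
#' @return An `emg_envelope` with `stage = "e3"`.
#' @export
exp_envelope <- function(e2) {
  stopifnot(inherits(e2, "emg_envelope"))
  v <- e2$values
  rng <- range(v)
  if (diff(rng) == 0) {
    warning("constant envelope; exponential stage returns all ones")
    out <- rep(1, length(v))
  } else {
    out <- 10^((v - rng[1]) / diff(rng))
  }
  new_envelope(out, e2$sampling_rate, e2$method, "e3", e2$source_method)
}

#' Compute an envelope chain up to a requested stage
#'
#' Convenience wrapper producing e1, e2 or e3 for either envelope method.
#'
#' @param record An [emg_record()].
#' @param method `"rms"` or `"fse"`.
#' @param stage `"e1"`, `"e2"` or `"e3"`.
#' @param window Stage-1 window in seconds.
#' @param smooth_window Stage-2 moving-average window in seconds.
#' @return An `emg_envelope` of the requested stage.
#' @export
compute_envelope <- function(record, method = c("rms", "fse"),
                             stage = c("e3", "e1", "e2"),
                             window = 0.250, smooth_window = 0.300) {
  method <- match.arg(method)
  stage <- match.arg(stage)
  e <- if (method == "rms") {
    rms_envelope(record, window = window)
  } else {
    fse_envelope(record, fse_params(window = window))
  }
  if (stage == "e1") return(e)
  e <- smooth_envelope(e, window = smooth_window)
  if (stage == "e2") return(e)
  exp_envelope(e)
}
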