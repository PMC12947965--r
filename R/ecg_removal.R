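#' Wavelet denoising of ECG interference with adaptive thresholds
#'
#' Decomposes the record to four levels with a Daubechies-4 wavelet. The
#' level-4 approximation (content below fs/32, i.e. 15.625 Hz at 500 Hz
#' sampling, dominated by P and T waves) is discarded, and detail
#' coefficients lying inside per-level windows around each R-peak are
#' truncated to an adaptive bound of `K = 5` times a robust scale
#' estimate. The window length grows linearly from `lb` (200 ms) at level
#' 1 to `ub` (300 ms) at level 4, mapped to coefficient indices at each
#' dyadic scale. The robust scale is 1.4826 x the median absolute detail
#' coefficient outside every R-window at that level.
#'
#' @param record An [emg_record()].
#' @param rpeaks An [rpeak_train()]; when empty, the truncation is applied
#'   globally with a warning.
#' @param k Threshold multiple of the robust scale.
#' @param lb,ub Lower and upper bounds of the threshold window, seconds.
#' @return The denoised [emg_record()] with `source_method = "wavelet"`.
#' @export
wavelet_denoise <- function(record, rpeaks, k = 5, lb = 0.200, ub = 0.300) {
  stopifnot(inherits(record, "emg_record"))
  fs <- record$sampling_rate
  x <- record$samples
  if (length(x) < 2^4 * length(DB4_H)) {
    stop("record too short for a 4-level decomposition")
  }
  dec <- dwt_periodized(x, levels = 4L)
  peaks <- if (inherits(rpeaks, "rpeak_train")) rpeaks$indices else integer(0)
  global <- length(peaks) == 0L
  if (global) {
    warning("no R-peaks supplied; applying global wavelet thresholding")
  }
  for (j in 1:4) {
    d <- dec$d[[j]]
    nd <- length(d)
    win_s <- lb + (ub - lb) * (j - 1) / 3
    half <- max(1L, round(win_s / 2 * fs / 2^j))
    inwin <- rep(FALSE, nd)
    for (r in peaks) {
      cidx <- round(r / 2^j)
      lo <- max(1L, cidx - half)
      hi <- min(nd, cidx + half)
      inwin[lo:hi] <- TRUE
    }
    ref <- if (global) abs(d) else abs(d[!inwin])
    sigma <- 1.4826 * stats::median(ref)
    if (!is.finite(sigma) || sigma == 0) next
    thr <- k * sigma
    target <- if (global) rep(TRUE, nd) else inwin
    d[target] <- pmin(pmax(d[target], -thr), thr)
    dec$d[[j]] <- d
  }
  dec$a <- numeric(length(dec$a))  # drop the sub-15.625 Hz approximation
  out <- record
  out$samples <- idwt_periodized(dec)
  out$source_method <- "wavelet"
  out
}

#' Gating of QRS complexes
#'
#' Optionally high-pass filters the record at 45 Hz (zero-phase,
#' 2nd-order Butterworth) to strip the low-frequency P/T-wave energy, then
#' replaces the samples in a 130 ms window centered on each R-peak with a
#' straight line joining the RMS of the 65 ms window immediately before
#' the gated segment and the RMS of the 65 ms window immediately after
#' it. The replacement is the (nonnegative) RMS magnitude trace itself:
#' downstream consumers are amplitude envelopes, which only see magnitude.
#'
#' @param record An [emg_record()].
#' @param rpeaks An [rpeak_train()].
#' @param highpass High-pass cutoff in Hz, or `NULL` to skip the filter
#'   (used when gating follows adaptive cancellation).
#' @return The gated [emg_record()].
#' @export
gate <- function(record, rpeaks, highpass = 45) {
  stopifnot(inherits(record, "emg_record"), inherits(rpeaks, "rpeak_train"))
  fs <- record$sampling_rate
  x <- record$samples
  n <- length(x)
  if (!is.null(highpass)) {
    hp <- signal::butter(2, highpass / (fs / 2), type = "high")
    x <- zerophase_filter(hp, x)
  }
  n_g <- round(0.130 * fs)
  half <- floor(n_g / 2)
  n_f <- round(0.065 * fs)
  for (r in rpeaks$indices) {
    lo <- max(1L, r - half)
    hi <- min(n, r - half + n_g - 1L)
    pre <- max(1L, lo - n_f):(lo - 1L)
    pre <- pre[pre >= 1L & pre < lo]
    post <- (hi + 1L):min(n, hi + n_f)
    post <- post[post > hi & post <= n]
    rms_pre <- if (length(pre)) rms(x[pre]) else NA_real_
    rms_post <- if (length(post)) rms(x[post]) else NA_real_
    if (is.na(rms_pre)) rms_pre <- rms_post
    if (is.na(rms_post)) rms_post <- rms_pre
    if (is.na(rms_pre)) next
    x[lo:hi] <- seq(rms_pre, rms_post, length.out = hi - lo + 1L)
  }
  out <- record
  out$samples <- x
  out$source_method <- if (record$source_method == "adaptive") {
    "adaptive_gating"
  } else {
    "gating"
  }
  out
}

# Build the averaged cardiac template and tile it at every R-peak.
# Segments span [-200, +400] ms around each peak; the 25% with the highest
# energy (those most likely to contain inspiratory EMG) are excluded from
# the average. Overlapping copies overwrite (a beat train, not a
# convolution).
cardiac_reference <- function(x, peaks, fs) {
  pre_n <- round(0.2 * fs)
  post_n <- round(0.4 * fs)
  n <- length(x)
  full <- peaks[peaks - pre_n >= 1L & peaks + post_n <= n]
  if (length(full) < 2L) stop("too few complete cardiac segments")
  seg <- t(vapply(full, function(r) x[(r - pre_n):(r + post_n)],
                  numeric(pre_n + post_n + 1L)))
  energy <- rowSums(seg^2)
  n_drop <- floor(0.25 * nrow(seg))
  keep <- if (n_drop > 0L) {
    order(energy)[seq_len(nrow(seg) - n_drop)]
  } else {
    seq_len(nrow(seg))
  }
  template <- colMeans(seg[keep, , drop = FALSE])
  ref <- numeric(n)
  for (r in peaks) {
    lo <- max(1L, r - pre_n)
    hi <- min(n, r + post_n)
    ref[lo:hi] <- template[(lo - (r - pre_n) + 1L):(hi - (r - pre_n) + 1L)]
  }
  list(reference = ref, template = template)
}

#' Adaptive LMS cancellation of ECG interference
#'
#' Synthesizes a cardiac reference from the record itself (an averaged
#' beat template tiled at every R-peak, excluding the 25% highest-energy
#' segments from the template average) and removes the component of the
#' record correlated with it using an LMS adaptive filter with taps
#' spanning 0.4 s. The adaptation constant is tuned by bisection on a
#' logarithmic grid until the energy of the cancellation output matches
#' the reference energy within 5%; if the filter diverges the step is
#' halved and the run restarted (at most 5 restarts).
#'
#' @param record An [emg_record()].
#' @param rpeaks An [rpeak_train()] with at least 8 peaks.
#' @return The residual [emg_record()] (primary minus cancellation) with
#'   `source_method = "adaptive"`.
#' @export
adaptive_cancel <- function(record, rpeaks) {
  stopifnot(inherits(record, "emg_record"), inherits(rpeaks, "rpeak_train"))
  if (length(rpeaks$indices) < 8L) {
    stop("adaptive cancellation needs at least 8 R-peaks")
  }
  fs <- record$sampling_rate
  x <- record$samples
  ref <- cardiac_reference(x, rpeaks$indices, fs)$reference
  M <- round(0.4 * fs)
  e_ref <- sum(ref^2)
  e_x <- sum(x^2)
  p_ref <- mean(ref^2)
  if (e_ref == 0 || p_ref == 0) {
    warning("cardiac reference has zero energy; record returned unchanged")
    out <- record
    out$source_method <- "adaptive"
    return(out)
  }

  run <- function(mu_norm, restarts = 5L) {
    mu <- mu_norm / (M * p_ref)
    for (i in seq_len(restarts + 1L)) {
      res <- lms_cancel_cpp(x, ref, M, mu)
      if (!res$diverged && sum(res$e^2) <= 2 * e_x) return(res)
      mu <- mu / 2
    }
    res
  }

  ratio_of <- function(res) sum(res$y^2) / e_ref
  grid <- 10^seq(-4, 0, by = 1)
  evals <- list()
  ratios <- numeric(0)
  for (g in grid) {
    res <- run(g)
    evals[[length(evals) + 1L]] <- res
    ratios <- c(ratios, ratio_of(res))
    if (abs(ratios[length(ratios)] - 1) <= 0.05) break
  }
  best_i <- which(abs(ratios - 1) <= 0.05)
  if (length(best_i)) {
    res <- evals[[best_i[1L]]]
  } else {
    # bisect between the largest under-shooting and smallest over-shooting
    lo_i <- which(ratios < 0.95)
    hi_i <- which(ratios > 1.05)
    if (length(lo_i) && length(hi_i)) {
      lo <- grid[max(lo_i[lo_i < min(hi_i)])]
      hi <- grid[min(hi_i)]
      res <- evals[[which.min(abs(ratios - 1))]]
      for (it in seq_len(12L)) {
        mid <- sqrt(lo * hi)
        rmid <- run(mid)
        rr <- ratio_of(rmid)
        if (abs(rr - 1) <= 0.05) {
          res <- rmid
          break
        }
        if (rr < 1) lo <- mid else hi <- mid
        res <- rmid
      }
    } else {
      res <- evals[[which.min(abs(ratios - 1))]]
      warning("LMS energy-match criterion not reached; using closest stable step")
    }
  }
  out <- record
  out$samples <- as.numeric(res$e)
  out$source_method <- "adaptive"
  out
}

#' Adaptive cancellation followed by gating
#'
#' Applies [adaptive_cancel()] and then [gate()] with the 45 Hz high-pass
#' stage disabled (the adaptive stage already removed the low-frequency
#' cardiac components), using the same 130 ms / 65 ms gating geometry.
#' This removes the residual high-frequency QRS spikes that the adaptive
#' filter leaves on some beats.
#'
#' @inheritParams adaptive_cancel
#' @return The processed [emg_record()] with
#'   `source_method = "adaptive_gating"`.
#' @export
adaptive_then_gate <- function(record, rpeaks) {
  gate(adaptive_cancel(record, rpeaks), rpeaks, highpass = NULL)
}
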