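#' Zero-phase Butterworth band-pass filter
#'
#' Conditions a raw EMGdi record with a 4th-order zero-phase Butterworth
#' band-pass, by default 5-200 Hz. The band-pass is realized as a cascade
#' of an order-`order` high-pass and an order-`order` low-pass section,
#' each applied forward and backward, which is numerically robust at the
#' very low normalized corner frequency of the 5 Hz edge.
#'
#' @param record An [emg_record()].
#' @param low,high Band edges in Hz. `high` is clipped to 0.95 x Nyquist
#'   with a warning when necessary.
#' @param order Butterworth section order.
#' @return The filtered [emg_record()].
#' @export
bandpass <- function(record, low = 5, high = 200, order = 4) {
  stopifnot(inherits(record, "emg_record"))
  fs <- record$sampling_rate
  nyq <- fs / 2
  if (high >= 0.95 * nyq) {
    high <- 0.95 * nyq
    warning(sprintf("upper band edge clipped to %.1f Hz (0.95 x Nyquist)", high))
  }
  if (low <= 0 || low >= high) stop("need 0 < low < high < Nyquist")
  if (length(record$samples) < 8 * order) {
    stop("record too short for the filter warm-up")
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  out <- record
  out$samples <- zerophase_filter(lp, zerophase_filter(hp, record$samples))
  out
}

# Power of x in [f0 - halfband, f0 + halfband] Hz from the periodogram.
band_power <- function(x, fs, f0, halfband = 1) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= (f0 - halfband) & freqs <= (f0 + halfband)
  sum(sp[sel])
}

# RBJ-style IIR notch biquad at f0 with quality factor Q.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Adaptive zero-phase notch filtering of mains interference
#'
#' Attenuates the mains fundamental and its harmonics with narrowband IIR
#' notch filters applied in zero phase. The notch bandwidth (Q factor) at
#' each harmonic is adjusted iteratively until the residual power in a
#' +/-1 Hz band at the harmonic is within 10% of the mean power in two
#' adjacent +/-1 Hz sidebands (centered 3 Hz below and above), i.e. the
#' line is attenuated into the local noise floor but not notched deeper
#' than it.
#'
#' @param record An [emg_record()].
#' @param base_freq Mains fundamental in Hz.
#' @param n_harmonics Number of harmonics to treat (all must lie below the
#'   Nyquist frequency).
#' @param q_start,q_step,max_iter Iteration controls: starting Q,
#'   multiplicative step, and iteration cap per harmonic.
#' @return The notch-filtered [emg_record()].
#' @export
notch_mains <- function(record, base_freq = 50, n_harmonics = 1,
                        q_start = 35, q_step = 1.25, max_iter = 20) {
  stopifnot(inherits(record, "emg_record"))
  fs <- record$sampling_rate
  if (base_freq * n_harmonics >= fs / 2) {
    stop("highest harmonic must lie below the Nyquist frequency")
  }
  x <- record$samples
  for (h in seq_len(n_harmonics)) {
    f0 <- base_freq * h
    side <- mean(c(band_power(x, fs, f0 - 3), band_power(x, fs, f0 + 3)))
    q <- q_start
    best <- NULL
    converged <- FALSE
    prev_ratio <- NA_real_
    for (it in seq_len(max_iter)) {
      flt <- design_notch(f0, fs, q)
      y <- zerophase_filter(flt, x)
      resid <- band_power(y, fs, f0)
      best <- y
      if (side <= 0) break
      ratio <- resid / side
      if (ratio >= 0.9 && ratio <= 1.1) {
        converged <- TRUE
        break
      }
      # a Q change that no longer moves the ratio means the residual has
      # reached the local noise floor; accept it
      if (!is.na(prev_ratio) && abs(ratio - prev_ratio) < 0.005) {
        converged <- TRUE
        break
      }
      prev_ratio <- ratio
      # residual too low -> notch too wide -> raise Q; too high -> lower Q
      q <- if (ratio < 0.9) q * q_step else q / q_step
    }
    if (!converged && side > 0) {
      warning(sprintf("notch at %g Hz: sideband criterion not met after %d iterations; keeping last Q",
                      f0, max_iter))
    }
    x <- best
  }
  out <- record
  out$samples <- x
  out
}

#' Detect R-peaks with a Pan-Tompkins style QRS detector
#'
#' The record is band-pass filtered to 5-40 Hz (zero phase) to enhance the
#' cardiac components, then passed through the classic derivative,
#' squaring and 150 ms moving-window integration stages. Peaks of the
#' integrated signal are screened with adaptive dual thresholds (200 ms
#' refractory period and RR-gap search-back), and each accepted detection
#' is refined to the local extremum of the 5-40 Hz signal within
#' +/-40 ms. Records without convincing cardiac activity yield a
#' low-confidence (possibly empty) train; downstream stages tolerate this.
#'
#' @param record An [emg_record()].
#' @return An [rpeak_train()].
#' @export
detect_r_peaks <- function(record) {
  stopifnot(inherits(record, "emg_record"))
  fs <- record$sampling_rate
  n <- length(record$samples)
  if (n / fs < 5) stop("record must be at least 5 s long for QRS detection")

  bp <- bandpass(record, low = 5, high = 40, order = 4)$samples
  der <- c(0, 0, diff(bp, lag = 4) / 8, 0, 0) * fs / 4
  sq <- der^2
  wh <- window_halves(0.150, fs)
  integ <- moving_mean(sq, wh$left, wh$right)

  # candidate peaks: local maxima of the integrated signal separated by the
  # 200 ms refractory period
  refr <- round(0.2 * fs)
  is_peak <- integ > c(-Inf, integ[-n]) & integ >= c(integ[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) > 1L) {
    # greedy by height under the refractory constraint
    pos <- cand[order(-integ[cand])]
    sel <- integer(0)
    for (p in pos) {
      if (!length(sel) || all(abs(sel - p) >= refr)) sel <- c(sel, p)
    }
    cand <- sort(sel)
  }
  if (!length(cand)) {
    warning("no QRS candidates found")
    return(rpeak_train(integer(0), fs, confidence = "low"))
  }

  init <- integ[seq_len(min(n, round(2 * fs)))]
  spki <- max(init)
  npki <- mean(init)
  thr1 <- function() npki + 0.25 * (spki - npki)
  accepted <- integer(0)
  rr_avg <- NA_real_
  for (p in cand) {
    if (integ[p] > thr1()) {
      if (length(accepted) && (p - accepted[length(accepted)]) < refr) next
      # search-back: long gap with a sub-threshold candidate above thr1/2
      if (length(accepted) && !is.na(rr_avg) &&
          (p - accepted[length(accepted)]) > 1.66 * rr_avg) {
        gap <- cand[cand > accepted[length(accepted)] + refr & cand < p - refr]
        gap <- gap[integ[gap] > 0.5 * thr1()]
        if (length(gap)) {
          gb <- gap[which.max(integ[gap])]
          accepted <- c(accepted, gb)
          spki <- 0.25 * integ[gb] + 0.75 * spki
        }
      }
      accepted <- c(accepted, p)
      spki <- 0.125 * integ[p] + 0.875 * spki
      if (length(accepted) >= 2L) {
        rrs <- diff(utils::tail(accepted, 8L))
        rr_avg <- mean(rrs)
      }
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
  }
  if (!length(accepted)) {
    warning("no QRS complexes above threshold")
    return(rpeak_train(integer(0), fs, confidence = "low"))
  }

  # refine to the local extremum of the 5-40 Hz signal within +/-40 ms
  half <- round(0.04 * fs)
  refined <- vapply(accepted, function(p) {
    lo <- max(1L, p - half)
    hi <- min(n, p + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1L) {
    keep <- c(TRUE, diff(refined) >= refr)
    while (!all(keep)) {
      # on conflicts keep the taller integrated peak
      i <- which(!keep)[1]
      if (integ[refined[i]] > integ[refined[i - 1L]]) {
        refined <- refined[-(i - 1L)]
      } else {
        refined <- refined[-i]
      }
      keep <- c(TRUE, diff(refined) >= refr)
    }
  }

  # confidence: peak prominence over background and RR regularity
  prom <- mean(integ[refined]) / (stats::median(integ) + .Machine$double.eps)
  rr_cv <- if (length(refined) > 2L) {
    stats::sd(diff(refined)) / mean(diff(refined))
  } else {
    Inf
  }
  conf <- if (prom >= 3 && rr_cv < 0.5) "high" else "low"
  rpeak_train(refined, fs, confidence = conf)
}

#' Build an ECG exclusion mask from an R-peak train
#'
#' Marks every sample within a window from 135 ms before to 365 ms after
#' each R-peak as excluded (`FALSE`); overlapping windows merge. The
#' window is a closed sample interval
#' `[r - round(0.135 fs), r + round(0.365 fs)]`.
#'
#' @param rpeaks An [rpeak_train()].
#' @param n_samples Length of the record the mask applies to.
#' @return A logical vector of length `n_samples`; `TRUE` marks samples
#'   kept (outside every cardiac window).
#' @export
ecg_exclusion_mask <- function(rpeaks, n_samples) {
  stopifnot(inherits(rpeaks, "rpeak_train"))
  if (length(rpeaks$indices) && max(rpeaks$indices) > n_samples) {
    stop("R-peak indices exceed the record length")
  }
  keep <- rep(TRUE, n_samples)
  fs <- rpeaks$sampling_rate
  pre <- round(0.135 * fs)
  post <- round(0.365 * fs)
  for (r in rpeaks$indices) {
    lo <- max(1L, r - pre)
    hi <- min(n_samples, r + post)
    keep[lo:hi] <- FALSE
  }
  keep
}

#' Convert an amplitude ratio to decibels
#'
#' @param ratio Positive amplitude ratio.
#' @return `20 log10(ratio)` in dB.
#' @export
ratio_to_db <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  20 * log10(ratio)
}

#' Inspiratory-to-basal signal-to-noise ratio per epoch
#'
#' For consecutive epochs (30 s by default), concatenates the samples
#' inside detected inspiratory intervals that survive the ECG exclusion
#' mask and those outside every interval (basal expiratory activity), and
#' reports `20 log10(RMS_insp / RMS_basal)` in dB. Epochs with less than
#' 250 ms of either class are flagged missing.
#'
#' @param record An [emg_record()].
#' @param cycles Data frame with `onset_s` and `offset_s` columns of
#'   accepted inspiratory intervals (sorted, non-overlapping).
#' @param mask Optional logical keep-mask from [ecg_exclusion_mask()];
#'   defaults to all-`TRUE`.
#' @param epoch_length Epoch duration in seconds.
#' @return A data frame with `epoch_start`, `epoch_length`, `value_db`
#'   (NA when missing) and `missing`.
#' @export
compute_i2bsnr <- function(record, cycles, mask = NULL, epoch_length = 30) {
  stopifnot(inherits(record, "emg_record"))
  n <- length(record$samples)
  if (n == 0L) stop("empty record")
  fs <- record$sampling_rate
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("mask length must match the record")
  t <- (seq_len(n) - 1) / fs

  insp <- rep(FALSE, n)
  if (nrow(cycles)) {
    ons <- cycles$onset_s
    offs <- cycles$offset_s
    if (is.unsorted(ons)) stop("cycles must be sorted by onset")
    idx <- findInterval(t, ons)
    insp <- idx >= 1L & t <= offs[pmax(idx, 1L)]
  }

  min_n <- round(0.25 * fs)
  starts <- seq(0, (n - 1) / fs, by = epoch_length)
  value <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    sel <- t >= starts[k] & t < starts[k] + epoch_length
    i_idx <- sel & insp & mask
    b_idx <- sel & !insp & mask
    if (sum(i_idx) >= min_n && sum(b_idx) >= min_n) {
      value[k] <- ratio_to_db(rms(record$samples[i_idx]) /
                                rms(record$samples[b_idx]))
    }
  }
  data.frame(epoch_start = starts, epoch_length = epoch_length,
             value_db = value, missing = is.na(value))
}

# Missing-epoch policy: carry the last valid value forward (and the first
# valid value backward for leading gaps), so the bias correction always has
# a quality estimate per segment.
fill_i2bsnr <- function(i2bsnr) {
  v <- i2bsnr$value_db
  if (all(is.na(v))) return(i2bsnr)
  for (k in seq_along(v)) {
    if (is.na(v[k]) && k > 1L) v[k] <- v[k - 1L]
  }
  for (k in rev(seq_along(v))) {
    if (is.na(v[k]) && k < length(v)) v[k] <- v[k + 1L]
  }
  i2bsnr$value_db <- v
  i2bsnr
}
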