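#' Construct a sampled single-channel EMG record
#'
#' An `emg_record` is the substrate of every pipeline stage: a numeric
#' sample vector with its sampling rate and unit metadata, plus a tag
#' recording which ECG-suppression method (if any) produced it.
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param label Channel label.
#' @param units Amplitude units (e.g. `"uV"` or `"a.u."` for synthetic
#'   signals).
#' @param source_method ECG-suppression provenance, one of `"none"`,
#'   `"wavelet"`, `"gating"`, `"adaptive"`, `"adaptive_gating"`.
#' @return An object of class `emg_record`.
#' @export
emg_record <- function(samples, sampling_rate, label = "EMGdi",
                       units = "a.u.", source_method = "none") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("record must contain at least one sample")
  if (!all(is.finite(samples))) stop("record samples must be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  source_method <- match.arg(source_method, c("none", "wavelet", "gating",
                                              "adaptive", "adaptive_gating"))
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         label = label, units = units, source_method = source_method),
    class = "emg_record"
  )
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %s: %d samples @ %g Hz (%.1f s), units %s, ecg removal: %s\n",
              x$label, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$units, x$source_method))
  invisible(x)
}

#' @export
length.emg_record <- function(x) length(x$samples)

#' Duration of a record in seconds
#' @param record An [emg_record()].
#' @return Duration in seconds.
#' @export
record_duration <- function(record) {
  length(record$samples) / record$sampling_rate
}

#' Construct a train of detected R-peak positions
#'
#' @param indices Strictly increasing 1-based sample indices.
#' @param sampling_rate Sampling rate in Hz.
#' @param confidence Either `"high"` or `"low"`; low-confidence trains arise
#'   when the QRS detector runs on records without visible cardiac activity.
#' @return An object of class `rpeak_train`.
#' @export
rpeak_train <- function(indices, sampling_rate, confidence = "high") {
  indices <- as.integer(indices)
  if (any(diff(indices) <= 0)) stop("R-peak indices must be strictly increasing")
  refractory <- 0.2 * sampling_rate
  if (length(indices) > 1L && any(diff(indices) < refractory)) {
    stop("R-peak train violates the 200 ms refractory period")
  }
  structure(list(indices = indices, sampling_rate = sampling_rate,
                 confidence = match.arg(confidence, c("high", "low"))),
            class = "rpeak_train")
}

#' @export
print.rpeak_train <- function(x, ...) {
  cat(sprintf("<rpeak_train> %d peaks @ %g Hz (confidence: %s)\n",
              length(x$indices), x$sampling_rate, x$confidence))
  invisible(x)
}

## ---- shared numeric helpers ------------------------------------------------

# Centered-window half widths: odd counts split evenly, even counts take the
# extra sample on the left, consistent with the zero-phase convention.
window_halves <- function(window_s, fs) {
  n <- max(2L, round(window_s * fs))
  list(n = n, left = ceiling((n - 1) / 2), right = floor((n - 1) / 2))
}

# Centered moving mean with edge shrinkage, O(n) via cumulative sums.
moving_mean <- function(x, n_left, n_right) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - n_left, 1L)
  hi <- pmin(i + n_right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

moving_rms <- function(x, n_left, n_right) {
  sqrt(pmax(moving_mean(x * x, n_left, n_right), 0))
}

rms <- function(x) sqrt(mean(x^2))

# Zero-phase IIR filtering: odd (anti-symmetric) reflection padding followed
# by a forward and a backward pass. More robust at the record edges than
# signal::filtfilt for the low normalized corner frequencies used here.
zerophase_filter <- function(flt, x) {
  b <- flt$b
  a <- flt$a
  n <- length(x)
  np <- min(n - 1L, 300L)
  if (np < 1L) stop("record too short for zero-phase filtering")
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xx <- c(pre, x, post)
  y <- signal::filter(b, a, xx)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(np + 1L):(np + n)])
}

# One-to-one matching of two interval sets by positive-length overlap.
# Seeds a greedy assignment preferring the longest overlaps, then grows it
# to a maximum bipartite matching with augmenting paths, so the matched
# count does not depend on fortunate tie-breaking. Returns a two-column
# matrix of (index in a, index in b).
match_intervals <- function(a_on, a_off, b_on, b_off) {
  na <- length(a_on)
  nb <- length(b_on)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  if (na == 0L || nb == 0L) return(empty)
  adj <- vector("list", na)
  cand <- list()
  for (i in seq_len(na)) {
    lo <- pmax(a_on[i], b_on)
    hi <- pmin(a_off[i], b_off)
    j <- which(hi > lo)
    adj[[i]] <- j[order(-(hi - lo)[j])]
    if (length(j)) cand[[length(cand) + 1L]] <- cbind(i, j, (hi - lo)[j])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3]), , drop = FALSE]
  match_a <- rep(NA_integer_, na)  # b index matched to each a
  match_b <- rep(NA_integer_, nb)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]
    j <- cand[k, 2]
    if (is.na(match_a[i]) && is.na(match_b[j])) {
      match_a[i] <- j
      match_b[j] <- i
    }
  }
  augment <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (is.na(match_b[j])) {
        match_a[i] <<- j
        match_b[j] <<- i
        return(TRUE)
      }
      prev <- match_b[j]
      res <- augment(prev, seen)
      if (res) {
        match_a[i] <<- j
        match_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in which(is.na(match_a))) {
    if (length(adj[[i]])) augment(i, logical(nb))
  }
  got <- which(!is.na(match_a))
  if (!length(got)) return(empty)
  cbind(a = got, b = match_a[got])
}
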