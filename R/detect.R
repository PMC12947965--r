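#' Detector configuration
#'
#' @param slow_ma Slow moving-average window in seconds (captures slow
#'   baseline changes, largely smoothing out respiratory fluctuations).
#' @param fast_ma Fast moving-average window in seconds (attenuates
#'   cardiac-related variations while preserving the respiratory
#'   component).
#' @param min_cycle Minimum accepted cycle duration in seconds.
#' @param amplitude_margin Required fractional excess of the mean in-cycle
#'   envelope over the flanking mean.
#' @param flank_fraction Flanking-window length as a fraction of the cycle
#'   duration.
#' @param kde_n Number of grid points for the kernel density estimate used
#'   by the onset/offset thresholds.
#' @param entropy_bins Number of equal-width histogram bins for the
#'   Shannon-entropy plausibility filter.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(slow_ma = 3, fast_ma = 1, min_cycle = 0.2,
                            amplitude_margin = 0.10, flank_fraction = 0.20,
                            kde_n = 512, entropy_bins = 32) {
  if (fast_ma >= slow_ma) stop("fast_ma must be shorter than slow_ma")
  if (amplitude_margin <= 0 || amplitude_margin >= 1) {
    stop("amplitude_margin must lie in (0, 1)")
  }
  if (flank_fraction <= 0 || flank_fraction >= 1) {
    stop("flank_fraction must lie in (0, 1)")
  }
  structure(list(slow_ma = slow_ma, fast_ma = fast_ma, min_cycle = min_cycle,
                 amplitude_margin = amplitude_margin,
                 flank_fraction = flank_fraction, kde_n = kde_n,
                 entropy_bins = entropy_bins),
            class = "detector_config")
}

add_flag <- function(flags, token) {
  ifelse(flags == "", token, paste(flags, token, sep = ";"))
}

has_flag <- function(flags, token) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(f) token %in% f, logical(1))
}

# "edge" is informational; only *_reject flags veto a cycle
is_accepted <- function(events) !grepl("reject", events$flags, fixed = TRUE)

#' Detect candidate inspiratory events by dual moving-average crossings
#'
#' Computes fast (1 s) and slow (3 s) centered moving averages of the
#' envelope. Each maximal run where the fast average exceeds the slow one,
#' bounded by an upward and the next downward crossing, is a candidate
#' event annotated at the temporal midpoint of the run. Runs touching the
#' record edges lack a bounding crossing and are discarded; runs shorter
#' than `min_cycle` are kept but flagged `duration_reject`.
#'
#' @param env An `emg_envelope`.
#' @param cfg A [detector_config()].
#' @return A data frame of events: `marker_s`, provisional interval bounds
#'   `int_start_s`/`int_end_s`, `onset_s`/`offset_s` (NA until
#'   localization) and a semicolon-joined `flags` string (`""` =
#'   accepted).
#' @export
detect_events <- function(env, cfg = detector_config()) {
  stopifnot(inherits(env, "emg_envelope"))
  fs <- env$sampling_rate
  v <- env$values
  n <- length(v)
  if (n <= cfg$slow_ma * fs) {
    stop("envelope shorter than the slow moving-average window")
  }
  whf <- window_halves(cfg$fast_ma, fs)
  whs <- window_halves(cfg$slow_ma, fs)
  fast <- moving_mean(v, whf$left, whf$right)
  slow <- moving_mean(v, whs$left, whs$right)
  above <- fast > slow
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & starts > 1L & ends < n)
  if (!length(runs)) {
    return(data.frame(marker_s = numeric(0), int_start_s = numeric(0),
                      int_end_s = numeric(0), onset_s = numeric(0),
                      offset_s = numeric(0), flags = character(0),
                      stringsAsFactors = FALSE))
  }
  s <- starts[runs]
  e <- ends[runs]
  dur <- (e - s + 1L) / fs
  ev <- data.frame(
    marker_s = ((s + e) / 2 - 1) / fs,
    int_start_s = (s - 1) / fs,
    int_end_s = (e - 1) / fs,
    onset_s = NA_real_,
    offset_s = NA_real_,
    flags = ifelse(dur < cfg$min_cycle, "duration_reject", ""),
    stringsAsFactors = FALSE
  )
  ev
}

#' Amplitude plausibility filter
#'
#' Compares the mean envelope inside each provisional event interval with
#' the mean over two flanking windows, each `flank_fraction` of the cycle
#' duration, immediately before and after the interval. Events whose
#' in-cycle mean is less than `1 + amplitude_margin` times the flanking
#' mean are flagged `amplitude_reject` (essentially flat envelopes, likely
#' residual artefacts). Flanks clipped by the record edge shrink and set
#' the `edge` flag.
#'
#' @param events Event data frame from [detect_events()].
#' @param env The `emg_envelope` the events were detected on.
#' @param cfg A [detector_config()].
#' @return The event data frame with updated flags.
#' @export
amplitude_filter <- function(events, env, cfg = detector_config()) {
  if (!nrow(events)) return(events)
  fs <- env$sampling_rate
  v <- env$values
  n <- length(v)
  for (i in which(is_accepted(events))) {
    s <- round(events$int_start_s[i] * fs) + 1L
    e <- round(events$int_end_s[i] * fs) + 1L
    dur_n <- e - s + 1L
    fl_n <- max(1L, round(cfg$flank_fraction * dur_n))
    pre <- max(1L, s - fl_n):(s - 1L)
    pre <- pre[pre >= 1L & pre < s]
    post <- (e + 1L):min(n, e + fl_n)
    post <- post[post > e & post <= n]
    if (length(pre) < fl_n || length(post) < fl_n) {
      events$flags[i] <- add_flag(events$flags[i], "edge")
    }
    flank <- c(v[pre], v[post])
    if (!length(flank)) next
    inside <- mean(v[s:e])
    if (inside < (1 + cfg$amplitude_margin) * mean(flank)) {
      events$flags[i] <- add_flag(events$flags[i], "amplitude_reject")
    }
  }
  events
}

# Mode of a sample via Gaussian KDE (Silverman's rule, argmax on a grid).
# Degenerate (constant) samples return the value plus a small epsilon so
# that a threshold at the mode is never crossed and the event dies by the
# minimum-duration rule.
kde_mode <- function(x, n_grid = 512) {
  if (length(x) < 2L || diff(range(x)) == 0) {
    return(max(x) + 1e-12 + 1e-9 * abs(max(x)))
  }
  d <- stats::density(x, bw = "nrd0", n = n_grid)
  d$x[which.max(d$y)]
}

#' Localize onset and offset with KDE-mode adaptive thresholds
#'
#' For each accepted event, the onset threshold is the mode (kernel
#' density estimate, Gaussian kernel, Silverman bandwidth) of the envelope
#' between the previous event's marker and the current marker (record
#' start for the first event); the offset threshold likewise between the
#' current and next markers. Starting from the detection marker the scan
#' moves backward (forward) until the envelope first dips to or below the
#' threshold; the onset (offset) is the last envelope sample exceeding
#' it. Scans stop at the adjacent marker or record edge, and the onset is
#' additionally bounded below by the previous accepted offset so accepted
#' cycles never overlap. Localized events shorter than 200 ms are flagged
#' `duration_reject`.
#'
#' @param events Event data frame with provisional intervals.
#' @param env The `emg_envelope`.
#' @param cfg A [detector_config()].
#' @return The event data frame with `onset_s`/`offset_s` filled for
#'   accepted events.
#' @export
localize_onset_offset <- function(events, env, cfg = detector_config()) {
  if (!nrow(events)) return(events)
  fs <- env$sampling_rate
  v <- env$values
  n <- length(v)
  acc <- which(is_accepted(events))
  if (!length(acc)) return(events)
  markers <- round(events$marker_s * fs) + 1L
  prev_offset_idx <- 0L
  for (pos in seq_along(acc)) {
    i <- acc[pos]
    m <- markers[i]
    lower <- if (pos > 1L) markers[acc[pos - 1L]] else 1L
    upper <- if (pos < length(acc)) markers[acc[pos + 1L]] else n
    lower <- max(lower, prev_offset_idx + 1L)

    thr_on <- kde_mode(v[lower:m], cfg$kde_n)
    thr_off <- kde_mode(v[m:upper], cfg$kde_n)

    # backward scan for the onset
    j <- m
    while (j > lower && v[j] > thr_on) j <- j - 1L
    onset_idx <- if (v[m] <= thr_on) {
      m
    } else if (v[j] > thr_on) {
      j        # reached the scan boundary while still above threshold
    } else {
      j + 1L   # last sample exceeding the threshold
    }

    # forward scan for the offset
    j <- m
    while (j < upper && v[j] > thr_off) j <- j + 1L
    offset_idx <- if (v[m] <= thr_off) {
      m
    } else if (v[j] > thr_off) {
      j
    } else {
      j - 1L
    }

    events$onset_s[i] <- (onset_idx - 1L) / fs
    events$offset_s[i] <- (offset_idx - 1L) / fs
    if ((offset_idx - onset_idx) / fs < 0.2) {
      events$flags[i] <- add_flag(events$flags[i], "duration_reject")
    } else {
      prev_offset_idx <- offset_idx
    }
  }
  events
}

shannon_entropy <- function(x, breaks) {
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Shannon-entropy plausibility filter
#'
#' Computes the Shannon entropy of the histogram of envelope values within
#' each accepted cycle (onset to offset) and compares it with the entropy
#' of the preceding and succeeding between-cycle phases. Genuine
#' inspiratory bursts sweep a wide range of envelope values and have high
#' entropy; a cycle whose entropy is lower than either adjacent phase is
#' flagged `entropy_reject`. Histograms use `entropy_bins` equal-width
#' bins over the pooled range of the three phases; missing phases (edge
#' events) are skipped.
#'
#' @param events Localized event data frame.
#' @param env The `emg_envelope`.
#' @param cfg A [detector_config()].
#' @return The event data frame with updated flags.
#' @export
entropy_filter <- function(events, env, cfg = detector_config()) {
  if (!nrow(events)) return(events)
  fs <- env$sampling_rate
  v <- env$values
  n <- length(v)
  acc <- which(is_accepted(events))
  if (!length(acc)) return(events)
  on_idx <- round(events$onset_s * fs) + 1L
  off_idx <- round(events$offset_s * fs) + 1L
  for (pos in seq_along(acc)) {
    i <- acc[pos]
    inside <- v[on_idx[i]:off_idx[i]]
    prev_end <- if (pos > 1L) off_idx[acc[pos - 1L]] else 0L
    next_start <- if (pos < length(acc)) on_idx[acc[pos + 1L]] else n + 1L
    before <- if (on_idx[i] - prev_end >= 3L) {
      v[(prev_end + 1L):(on_idx[i] - 1L)]
    } else {
      NULL
    }
    after <- if (next_start - off_idx[i] >= 3L) {
      v[(off_idx[i] + 1L):(next_start - 1L)]
    } else {
      NULL
    }
    if (is.null(before) && is.null(after)) next
    rng <- range(c(inside, before, after))
    if (diff(rng) == 0) next
    breaks <- seq(rng[1], rng[2], length.out = cfg$entropy_bins + 1L)
    h_in <- shannon_entropy(inside, breaks)
    rej <- FALSE
    if (!is.null(before) && h_in < shannon_entropy(before, breaks)) rej <- TRUE
    if (!is.null(after) && h_in < shannon_entropy(after, breaks)) rej <- TRUE
    if (rej) events$flags[i] <- add_flag(events$flags[i], "entropy_reject")
  }
  events
}

#' Full cycle detection chain on an envelope
#'
#' Runs [detect_events()], [amplitude_filter()], [localize_onset_offset()]
#' and [entropy_filter()] in sequence (amplitude filtering precedes
#' localization, matching the order in which the criteria are defined).
#'
#' @param env An `emg_envelope`.
#' @param cfg A [detector_config()].
#' @return An event data frame; rows with empty `flags` are the accepted
#'   cycles.
#' @export
detect_cycles <- function(env, cfg = detector_config()) {
  ev <- detect_events(env, cfg)
  ev <- amplitude_filter(ev, env, cfg)
  ev <- localize_onset_offset(ev, env, cfg)
  ev <- entropy_filter(ev, env, cfg)
  attr(ev, "config") <- cfg
  ev
}

#' Accepted cycles from an event table
#'
#' @param events Event data frame from [detect_cycles()].
#' @return The subset of events with no rejection flags (the `edge` flag
#'   alone does not reject a cycle).
#' @export
accepted_cycles <- function(events) {
  events[is_accepted(events), , drop = FALSE]
}
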