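# Independent brute-force oracles used across the suite.

rms <- function(x) sqrt(mean(x^2))

# O(n^2) sample entropy of one window with a fixed tolerance r: direct pair
# enumeration over templates of length m (and their m+1 extensions).
fse_brute <- function(x, r, m = 1) {
  n <- length(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  list(value = if (A > 0 && B > 0) -log(A / B) else NA_real_, A = A, B = B)
}

# Sliding-window brute-force fSE with centered windows and edge shrinkage.
sliding_fse_brute <- function(x, n_left, n_right, r, m = 1) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - n_left):min(n, i + n_right)]
    fse_brute(w, r, m)$value
  }, numeric(1))
}

# Brute-force sliding statistics with shrinking centered windows.
sliding_stat_brute <- function(x, n_left, n_right, f) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    f(x[max(1L, i - n_left):min(n, i + n_right)])
  }, numeric(1))
}

# Total length (in samples) of the union of closed integer intervals.
interval_union_count <- function(lo, hi, n) {
  covered <- logical(n)
  for (k in seq_along(lo)) {
    covered[max(1L, lo[k]):min(n, hi[k])] <- TRUE
  }
  sum(covered)
}

# Direct scan for runs where fast > slow bounded by crossings (no run may
# touch either record edge).
crossing_runs_oracle <- function(fast, slow) {
  above <- fast > slow
  n <- length(above)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (i > 1L && j < n) runs[[length(runs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

# Exhaustive maximum one-to-one matching size between two interval sets
# under the positive-overlap relation (recursion over the first set).
max_matching_brute <- function(a_on, a_off, b_on, b_off) {
  na <- length(a_on)
  nb <- length(b_on)
  ov <- function(i, j) min(a_off[i], b_off[j]) - max(a_on[i], b_on[j]) > 0
  rec <- function(i, used) {
    if (i > na) return(0L)
    best <- rec(i + 1L, used)  # leave a_i unmatched
    for (j in seq_len(nb)) {
      if (!used[j] && ov(i, j)) {
        used2 <- used
        used2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used2))
      }
    }
    best
  }
  rec(1L, logical(nb))
}

# Random non-overlapping sorted interval set on [0, span].
random_interval_set <- function(n, span = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gaps <- stats::runif(n, 0.2, span / n)
  lens <- stats::runif(n, 0.3, 1.5)
  onset <- cumsum(gaps + c(0, lens[-n]))
  data.frame(onset_s = onset, offset_s = onset + lens)
}

# Short synthetic record with ECG, shared by several suites.
quick_ecg_sim <- function(seed, n_cycles = 15, rms_ratio = 1.5,
                          heart_rate = 60, qrs_amplitude = 8) {
  simulate_emgdi(simulation_spec(
    n_cycles = n_cycles, rms_ratio = rms_ratio, seed = seed,
    ecg = ecg_spec(heart_rate = heart_rate, qrs_amplitude = qrs_amplitude)))
}
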