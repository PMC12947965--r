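fs <- 500

# Shared contaminated record: modest inspiratory activity with a strong
# cardiac artifact, plus index sets for QRS-centered windows and
# ECG-free mid-inspiratory segments.
make_contaminated <- function(seed = 2, rms_ratio = 1.5) {
  sim <- quick_ecg_sim(seed = seed, n_cycles = 30, rms_ratio = rms_ratio,
                       heart_rate = 60, qrs_amplitude = 8)
  n <- length(sim$record$samples)
  tru <- sim$rpeaks$indices
  qrs_idx <- unique(unlist(lapply(tru, function(r) {
    max(1L, r - 32L):min(n, r + 32L)
  })))
  t <- (seq_len(n) - 1) / fs
  near_ecg <- unique(unlist(lapply(tru, function(r) {
    max(1L, r - 125L):min(n, r + 250L)
  })))
  free_idx <- setdiff(which((t %% 2) >= 0.6 & (t %% 2) <= 1.4), near_ecg)
  list(sim = sim, qrs = qrs_idx, free = free_idx, n = n)
}

test_that("all four suppression methods preserve length and rate", {
  cc <- make_contaminated()
  rp <- detect_r_peaks(cc$sim$record)
  for (f in list(function(r) wavelet_denoise(r, rp),
                 function(r) gate(r, rp),
                 function(r) adaptive_cancel(r, rp),
                 function(r) adaptive_then_gate(r, rp))) {
    out <- f(cc$sim$record)
    expect_length(out$samples, cc$n)
    expect_equal(out$sampling_rate, fs)
  }
})

test_that("wavelet denoising truncates QRS energy and preserves inspiration", {
  cc <- make_contaminated()
  rp <- detect_r_peaks(cc$sim$record)
  out <- wavelet_denoise(cc$sim$record, rp)
  x0 <- cc$sim$record$samples
  expect_lt(rms(out$samples[cc$qrs]) / rms(x0[cc$qrs]), 0.5)
  expect_lt(abs(rms(out$samples[cc$free]) / rms(x0[cc$free]) - 1), 0.15)
  expect_identical(out$source_method, "wavelet")

  # zero input -> zero output (linearity, zero thresholds)
  zero <- emg_record(rep(0, 4000), fs)
  expect_warning(z <- wavelet_denoise(zero, rpeak_train(integer(0), fs)),
                 "global")
  expect_equal(max(abs(z$samples)), 0)
})

test_that("gating replaces the 130 ms QRS window with the flank RMS line", {
  # flat unit-RMS noise: the replaced segment is about constant at flank RMS
  set.seed(5)
  rec <- emg_record(rnorm(6000), fs)
  rp <- rpeak_train(3000L, fs)
  out <- gate(rec, rp, highpass = NULL)
  seg <- out$samples[(3000 - 32):(3000 - 32 + 64)]
  expect_length(seg, 65)  # 130 ms at 500 Hz
  expect_lt(diff(range(seg)), 0.75)  # a line, not noise
  expect_lt(abs(mean(seg) - 1), 0.35)  # near the unit flank RMS

  # outside the QRS windows gating is the identity on the filtered signal
  hp <- signal::butter(2, 45 / 250, type = "high")
  ref <- emgdi:::zerophase_filter(hp, rec$samples)
  out45 <- gate(rec, rp, highpass = 45)
  outside <- setdiff(seq_len(6000), (3000 - 32):(3000 + 32))
  expect_identical(out45$samples[outside], ref[outside])

  # contaminated record: QRS-window RMS lands within 20% of the flank level
  cc <- make_contaminated()
  rp2 <- detect_r_peaks(cc$sim$record)
  g <- gate(cc$sim$record, rp2)
  for (r in cc$sim$rpeaks$indices[5:10]) {
    seg <- g$samples[(r - 32):(r + 32)]
    flank <- g$samples[c((r - 97):(r - 33), (r + 33):(r + 97))]
    expect_lt(abs(rms(seg) / rms(flank) - 1), 0.30)
  }
})

test_that("adaptive cancellation removes the correlated beat train only", {
  cc <- make_contaminated()
  rp <- detect_r_peaks(cc$sim$record)

  # pure tiled template: residual energy collapses
  ref <- emgdi:::cardiac_reference(cc$sim$record$samples, rp$indices, fs)
  pure <- emg_record(ref$reference + 1e-9 * stats::rnorm(cc$n), fs)
  out <- adaptive_cancel(pure, rp)
  expect_lt(sum(out$samples^2) / sum(pure$samples^2), 0.05)

  # uncorrelated reference leaves the primary essentially unchanged
  set.seed(6)
  noise <- emg_record(rnorm(30000), fs)
  fake <- rpeak_train(seq(250L, 29500L, by = 450L), fs)
  outn <- suppressWarnings(adaptive_cancel(noise, fake))
  expect_lt(abs(stats::sd(outn$samples) / stats::sd(noise$samples) - 1), 0.10)

  # contaminated record: QRS RMS down >= 40%, inspiration changed <= 10%
  x0 <- cc$sim$record$samples
  outc <- adaptive_cancel(cc$sim$record, rp)
  expect_lt(rms(outc$samples[cc$qrs]) / rms(x0[cc$qrs]), 0.6)
  expect_lt(abs(rms(outc$samples[cc$free]) / rms(x0[cc$free]) - 1), 0.10)
  expect_error(adaptive_cancel(cc$sim$record, rpeak_train(c(500L, 900L), fs)),
               "8 R-peaks")
})

test_that("adaptive + gating flattens QRS windows at least as much as adaptive", {
  cc <- make_contaminated()
  rp <- detect_r_peaks(cc$sim$record)
  a <- adaptive_cancel(cc$sim$record, rp)
  ag <- adaptive_then_gate(cc$sim$record, rp)
  expect_identical(ag$source_method, "adaptive_gating")
  expect_lte(rms(ag$samples[cc$qrs]), rms(a$samples[cc$qrs]) * 1.001)
  # inspiratory segments away from QRS complexes survive
  x0 <- cc$sim$record$samples
  expect_lt(abs(rms(ag$samples[cc$free]) / rms(x0[cc$free]) - 1), 0.15)
})

test_that("every method raises the measured I2BSNR of contaminated records", {
  # paired comparison across seeds and signal-quality levels
  seeds <- 1:20
  ratios <- c(1.2, 2, 5, 10)
  gains <- array(NA_real_, c(length(ratios), length(seeds), 4),
                 dimnames = list(NULL, NULL,
                                 c("wavelet", "gating", "adaptive",
                                   "adaptive_gating")))
  for (ri in seq_along(ratios)) {
    for (si in seq_along(seeds)) {
      sim <- quick_ecg_sim(seed = 100 + 37 * si + ri, n_cycles = 10,
                           rms_ratio = ratios[ri], qrs_amplitude = 8)
      rp <- sim$rpeaks  # generator truth isolates suppression from detection
      snr_of <- function(rec) {
        compute_i2bsnr(rec, sim$truth, epoch_length = 100)$value_db[1]
      }
      base <- snr_of(sim$record)
      gains[ri, si, "wavelet"] <- snr_of(wavelet_denoise(sim$record, rp)) - base
      gains[ri, si, "gating"] <- snr_of(gate(sim$record, rp)) - base
      a <- adaptive_cancel(sim$record, rp)
      gains[ri, si, "adaptive"] <- snr_of(a) - base
      gains[ri, si, "adaptive_gating"] <-
        snr_of(gate(a, rp, highpass = NULL)) - base
    }
  }
  for (m in dimnames(gains)[[3]]) {
    for (ri in seq_along(ratios)) {
      expect_gt(mean(gains[ri, , m]), 0)
    }
  }
})
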