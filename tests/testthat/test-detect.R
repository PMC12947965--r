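fs <- 50  # envelope-level tests run at a reduced rate for speed

test_that("detector configuration enforces its invariants", {
  expect_error(detector_config(slow_ma = 1, fast_ma = 2), "shorter")
  expect_error(detector_config(amplitude_margin = 0), "amplitude_margin")
  expect_error(detector_config(flank_fraction = 1.2), "flank_fraction")
})

test_that("a flat envelope yields no events", {
  env <- emg_envelope(rep(1, 1000), fs)
  expect_equal(nrow(detect_events(env)), 0)
  expect_error(detect_events(emg_envelope(rep(1, 100), fs)), "shorter")
})

test_that("a rectangular burst is annotated at its midpoint", {
  v <- rep(0.1, 30 * fs)
  t0 <- 15
  v[(t0 - 0.5) * fs:((t0 + 0.5) * fs)] <- 1
  v <- v[1:(30 * fs)]
  env <- emg_envelope(v, fs)
  ev <- detect_events(env)
  acc <- ev[emgdi:::is_accepted(ev), ]
  expect_equal(nrow(acc), 1)
  expect_lt(abs(acc$marker_s - t0), 2 / fs + 0.05)
})

test_that("event extraction agrees with a crossing-scan oracle", {
  set.seed(31)
  for (rep in 1:10) {
    raw <- stats::filter(rnorm(1500), rep(1 / 30, 30), circular = TRUE)
    v <- as.numeric(raw) + 2
    env <- emg_envelope(v - min(v) + 0.01, fs)
    ev <- detect_events(env, detector_config(min_cycle = 1e-9))
    whf <- emgdi:::window_halves(1, fs)
    whs <- emgdi:::window_halves(3, fs)
    fast <- emgdi:::moving_mean(env$values, whf$left, whf$right)
    slow <- emgdi:::moving_mean(env$values, whs$left, whs$right)
    runs <- crossing_runs_oracle(fast, slow)
    expect_equal(nrow(ev), length(runs))
    if (length(runs)) {
      starts <- vapply(runs, `[[`, numeric(1), "start")
      ends <- vapply(runs, `[[`, numeric(1), "end")
      expect_equal(ev$marker_s, ((starts + ends) / 2 - 1) / fs)
    }
  }
})

test_that("the amplitude filter applies the 10% margin and 200 ms rules", {
  mk_env_events <- function(inside, flank, dur = 1) {
    v <- rep(flank, 20 * fs)
    s <- 10 * fs
    e <- s + dur * fs - 1
    v[s:e] <- inside
    list(env = emg_envelope(v, fs),
         ev = data.frame(marker_s = (s + e) / 2 / fs,
                         int_start_s = (s - 1) / fs, int_end_s = (e - 1) / fs,
                         onset_s = NA_real_, offset_s = NA_real_,
                         flags = "", stringsAsFactors = FALSE))
  }
  # inside mean equal to the flanks: margin unmet -> rejected
  z <- mk_env_events(1, 1)
  expect_true(grepl("amplitude_reject",
                    amplitude_filter(z$ev, z$env)$flags[1]))
  # 20% above the flanks with a 1 s duration -> kept
  z <- mk_env_events(1.2, 1)
  expect_identical(amplitude_filter(z$ev, z$env)$flags[1], "")
  # 150 ms duration is rejected regardless of amplitude
  z <- mk_env_events(5, 1, dur = 0.15)
  z$ev$flags <- "duration_reject"  # as flagged by detect_events
  out <- amplitude_filter(z$ev, z$env)
  expect_true(grepl("duration_reject", out$flags[1]))
})

test_that("onset/offset localization recovers trapezoid edges", {
  b <- 1
  p <- 5
  v <- rep(b, 40 * fs)
  ramp_n <- round(0.2 * fs)
  s <- 20 * fs
  up <- seq(b, p, length.out = ramp_n)
  plateau <- rep(p, round(0.8 * fs))
  down <- seq(p, b, length.out = ramp_n)
  burst <- c(up, plateau, down)
  v[s:(s + length(burst) - 1)] <- burst
  set.seed(2)
  v <- v + rnorm(length(v), 0, 1e-3)  # break exact ties only
  env <- emg_envelope(v, fs)
  ev <- detect_cycles(env)
  acc <- accepted_cycles(ev)
  expect_equal(nrow(acc), 1)
  # geometric edges of the burst, in seconds
  edge_on <- (s - 1) / fs
  edge_off <- (s + length(burst) - 2) / fs
  expect_lt(abs(acc$onset_s - edge_on), 3 / fs)
  expect_lt(abs(acc$offset_s - edge_off), 3 / fs)
  # symmetric burst: marker splits the cycle evenly
  expect_lt(abs((acc$marker_s - acc$onset_s) - (acc$offset_s - acc$marker_s)),
            2 / fs)
})

test_that("the entropy filter rejects flat in-cycle envelopes", {
  set.seed(4)
  n <- 30 * fs
  v <- runif(n, 0.5, 1.5)
  s <- 14 * fs
  e <- 16 * fs
  v[s:e] <- 1.0  # constant inside the cycle: zero entropy
  env <- emg_envelope(v, fs)
  ev <- data.frame(marker_s = 15, int_start_s = (s - 1) / fs,
                   int_end_s = (e - 1) / fs,
                   onset_s = (s - 1) / fs, offset_s = (e - 1) / fs,
                   flags = "", stringsAsFactors = FALSE)
  expect_true(grepl("entropy_reject", entropy_filter(ev, env)$flags[1]))

  # a cycle sweeping a wide range between quiet phases is kept
  v2 <- rep(1, n) + rnorm(n, 0, 0.01)
  v2[s:e] <- seq(1, 5, length.out = e - s + 1)
  ev2 <- ev
  expect_identical(entropy_filter(ev2, emg_envelope(v2, fs))$flags[1], "")
})

test_that("the full chain recovers every simulated cycle with fSE-e3", {
  sim <- simulate_emgdi(simulation_spec(n_cycles = 50, rms_ratio = 10, seed = 41))
  env <- compute_envelope(sim$record, "fse", "e3")
  acc <- accepted_cycles(detect_cycles(env))
  expect_equal(nrow(acc), 50)
  # one marker inside each true inspiration
  hits <- vapply(seq_len(50), function(k) {
    any(acc$marker_s >= sim$truth$onset_s[k] &
          acc$marker_s <= sim$truth$offset_s[k])
  }, logical(1))
  expect_true(all(hits))
})

test_that("accepted cycles never overlap and markers increase", {
  set.seed(51)
  for (seed in 1:5) {
    sim <- simulate_emgdi(simulation_spec(n_cycles = 20, rms_ratio = 3,
                                          seed = 60 + seed))
    acc <- accepted_cycles(detect_cycles(compute_envelope(sim$record, "rms", "e2")))
    if (nrow(acc) > 1) {
      expect_true(all(diff(acc$marker_s) > 0))
      expect_true(all(acc$onset_s[-1] >= acc$offset_s[-nrow(acc)]))
    }
    expect_true(all(acc$offset_s - acc$onset_s >= 0.2))
  }
})

test_that("the entropy filter passes nearly all true cycles at high SNR", {
  sim <- simulate_emgdi(simulation_spec(n_cycles = 40, rms_ratio = 5, seed = 71))
  env <- compute_envelope(sim$record, "rms", "e2")
  ev <- detect_cycles(env)
  n_entropy_rej <- sum(grepl("entropy_reject", ev$flags))
  expect_lte(n_entropy_rej, ceiling(0.05 * 40))
})
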