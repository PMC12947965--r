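#' Characterize onset/offset timing bias over a signal-quality grid
#'
#' Simulates Gaussian-white-noise EMGdi records (no ECG) at each
#' inspiratory-to-basal SNR level, runs the envelope and cycle-detection
#' chain, matches detections to the known ground truth by interval
#' overlap, and records the mean error (ME) and standard deviation of
#' `detected - true` onset and offset times per level. Levels where fewer
#' than half of the true cycles are detected are flagged low-confidence.
#'
#' @param levels_db I2BSNR grid in dB, strictly increasing, within
#'   (0, 40].
#' @param n_cycles Respiratory cycles simulated per level.
#' @param seed Base integer seed; level i uses `seed + i`.
#' @param method Envelope method, `"rms"` or `"fse"`.
#' @param stage Envelope stage, `"e1"`, `"e2"` or `"e3"`.
#' @param cfg A [detector_config()].
#' @param sampling_rate,cycle_period Simulation conditions.
#' @return A `bias_table` data frame with columns `i2bsnr_db`, `onset_me`,
#'   `onset_sd`, `offset_me`, `offset_sd`, `n_matched`, `n_true`,
#'   `low_confidence`, with the method tag stored as attributes.
#' @export
run_bias_simulation <- function(levels_db, n_cycles = 200, seed = 1,
                                method = c("rms", "fse"),
                                stage = c("e3", "e1", "e2"),
                                cfg = detector_config(),
                                sampling_rate = 500, cycle_period = 2) {
  method <- match.arg(method)
  stage <- match.arg(stage)
  if (any(levels_db <= 0) || any(levels_db > 40)) {
    stop("levels must lie within (0, 40] dB")
  }
  rows <- lapply(seq_along(levels_db), function(i) {
    ratio <- 10^(levels_db[i] / 20)
    sim <- simulate_emgdi(simulation_spec(
      n_cycles = n_cycles, rms_ratio = ratio, seed = seed + i,
      sampling_rate = sampling_rate, cycle_period = cycle_period))
    env <- compute_envelope(sim$record, method = method, stage = stage)
    det <- accepted_cycles(detect_cycles(env, cfg))
    err <- match_timing_errors(det, sim$truth)
    data.frame(i2bsnr_db = levels_db[i],
               onset_me = mean(err$onset_err),
               onset_sd = stats::sd(err$onset_err),
               offset_me = mean(err$offset_err),
               offset_sd = stats::sd(err$offset_err),
               n_matched = nrow(err),
               n_true = nrow(sim$truth),
               low_confidence = nrow(err) < 0.5 * nrow(sim$truth))
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "stage") <- stage
  class(out) <- c("bias_table", "data.frame")
  out
}

# Match detected cycles to ground-truth cycles by interval overlap and
# return per-cycle timing errors (detected - true), in seconds.
match_timing_errors <- function(detected, truth) {
  pairs <- match_intervals(detected$onset_s, detected$offset_s,
                           truth$onset_s, truth$offset_s)
  data.frame(
    onset_err = detected$onset_s[pairs[, "a"]] - truth$onset_s[pairs[, "b"]],
    offset_err = detected$offset_s[pairs[, "a"]] - truth$offset_s[pairs[, "b"]]
  )
}

double_exp <- function(x, a, b, cc, d) a * exp(b * x) + cc * exp(d * x)

fit_one_marker <- function(x, y) {
  starts <- list()
  mag <- max(abs(y), 1e-4)
  for (sa in c(1, -1)) {
    for (sc in c(1, -1)) {
      for (bd in list(c(-0.5, -0.05), c(-0.05, -0.5), c(-1e-3, -0.3))) {
        starts[[length(starts) + 1L]] <-
          c(a = sa * mag, b = bd[1], cc = sc * mag / 2, d = bd[2])
      }
    }
  }
  best <- NULL
  best_rmse <- Inf
  dat <- data.frame(x = x, y = y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x) + cc * exp(d * x), data = dat,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    co <- stats::coef(fit)
    if (!all(is.finite(double_exp(x, co["a"], co["b"], co["cc"], co["d"])))) next
    r <- sqrt(mean(stats::resid(fit)^2))
    if (r < best_rmse) {
      best <- co
      best_rmse <- r
    }
  }
  if (is.null(best)) {
    # fall back to a single exponential (c term dropped)
    warning("double-exponential fit failed on every start; ",
            "falling back to a single exponential")
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), data = dat,
                        start = list(a = y[1], b = -0.1)),
      error = function(e) NULL)
    if (is.null(fit)) {
      best <- c(a = mean(y), b = 0, cc = 0, d = 0)
      best_rmse <- sqrt(mean((y - mean(y))^2))
    } else {
      co <- stats::coef(fit)
      best <- c(a = co[["a"]], b = co[["b"]], cc = 0, d = 0)
      best_rmse <- sqrt(mean(stats::resid(fit)^2))
    }
  }
  list(coef = best, rmse = best_rmse)
}

#' Fit the double-exponential timing-correction model
#'
#' Fits `c(x) = a exp(b x) + c exp(d x)` (x = I2BSNR in dB) to the onset
#' and offset mean errors of a [run_bias_simulation()] table by nonlinear
#' least squares, multi-starting over the sign patterns of `(a, c)` and
#' decay-rate initializations, and keeping the best-RMSE fit. Outside the
#' fitted grid the correction is clamped to the range endpoints (the
#' exponentials are not trusted to extrapolate).
#'
#' @param table A `bias_table`.
#' @return A `correction_model` with onset/offset coefficient quadruples,
#'   the method tag, the valid I2BSNR range and per-marker fit RMSE.
#' @export
fit_correction <- function(table) {
  stopifnot(inherits(table, "bias_table") || is.data.frame(table))
  if (nrow(table) < 6L) stop("need at least 6 grid points to fit")
  x <- table$i2bsnr_db
  method <- attr(table, "method") %||% "custom"
  stage <- attr(table, "stage") %||% "custom"
  if (method == "rms" && stage == "e3") {
    warning("the exponential correction model is poorly suited to RMS-e3 ",
            "onsets; interpret corrected onsets with care")
  }
  on_fit <- fit_one_marker(x, table$onset_me)
  off_fit <- fit_one_marker(x, table$offset_me)
  structure(
    list(onset = on_fit$coef, offset = off_fit$coef,
         method = method, stage = stage,
         valid_range_db = range(x),
         fit_rmse = c(onset = on_fit$rmse, offset = off_fit$rmse)),
    class = "correction_model"
  )
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %s-%s, valid %g-%g dB\n", x$method,
              x$stage, x$valid_range_db[1], x$valid_range_db[2]))
  cat(sprintf("  onset : a=%.4g b=%.4g c=%.4g d=%.4g (rmse %.1f ms)\n",
              x$onset["a"], x$onset["b"], x$onset["cc"], x$onset["d"],
              1000 * x$fit_rmse["onset"]))
  cat(sprintf("  offset: a=%.4g b=%.4g c=%.4g d=%.4g (rmse %.1f ms)\n",
              x$offset["a"], x$offset["b"], x$offset["cc"], x$offset["d"],
              1000 * x$fit_rmse["offset"]))
  invisible(x)
}

#' Evaluate a fitted correction at given signal-quality values
#'
#' @param model A `correction_model`.
#' @param i2bsnr_db I2BSNR values in dB (clamped to the fitted range).
#' @param marker `"onset"` or `"offset"`.
#' @return Predicted timing error in seconds.
#' @export
eval_correction <- function(model, i2bsnr_db, marker = c("onset", "offset")) {
  marker <- match.arg(marker)
  x <- pmin(pmax(i2bsnr_db, model$valid_range_db[1]), model$valid_range_db[2])
  co <- model[[marker]]
  double_exp(x, co["a"], co["b"], co["cc"], co["d"])
}

#' Apply the signal-quality-driven timing correction to detected cycles
#'
#' Each cycle is assigned to the epoch containing its marker; the fitted
#' mean timing error at that epoch's I2BSNR (carried forward over missing
#' epochs, clamped to the model's valid range) is subtracted from the
#' detected onset and offset. The sign convention is `error = detected -
#' true`, so subtracting the fitted error removes the systematic bias.
#' Flags and all other columns are preserved.
#'
#' @param cycles Event data frame with `marker_s`, `onset_s`, `offset_s`.
#' @param i2bsnr Data frame from [compute_i2bsnr()].
#' @param model A `correction_model`.
#' @return The cycles with `onset_corrected_s` and `offset_corrected_s`
#'   columns added.
#' @export
apply_correction <- function(cycles, i2bsnr, model) {
  stopifnot(inherits(model, "correction_model"))
  if (!nrow(cycles)) {
    cycles$onset_corrected_s <- numeric(0)
    cycles$offset_corrected_s <- numeric(0)
    return(cycles)
  }
  filled <- fill_i2bsnr(i2bsnr)
  if (all(is.na(filled$value_db))) {
    stop("no valid I2BSNR epoch available for correction")
  }
  epoch <- findInterval(cycles$marker_s, filled$epoch_start)
  epoch <- pmin(pmax(epoch, 1L), nrow(filled))
  x <- filled$value_db[epoch]
  cycles$onset_corrected_s <- cycles$onset_s -
    eval_correction(model, x, "onset")
  cycles$offset_corrected_s <- cycles$offset_s -
    eval_correction(model, x, "offset")
  cycles
}

`%||%` <- function(a, b) if (is.null(a)) b else a
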