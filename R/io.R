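#' Read a record from a CSV file
#'
#' Accepts either a two-column CSV with header `time_s,amplitude` (the
#' sampling rate is inferred from the median time step) or a single
#' `amplitude` column with the sampling rate supplied via `fs`.
#'
#' @param path Path to the file.
#' @param fs Sampling rate in Hz, required for single-column files.
#' @param label,units Metadata for the returned record.
#' @return An [emg_record()].
#' @export
read_record <- function(path, fs = NULL, label = "EMGdi", units = "a.u.") {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path)
  if (all(c("time_s", "amplitude") %in% names(dat))) {
    dt <- stats::median(diff(dat$time_s))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time_s")
    emg_record(dat$amplitude, 1 / dt, label = label, units = units)
  } else if (ncol(dat) == 1L) {
    if (is.null(fs)) {
      stop("single-column CSV requires an explicit sampling rate (fs)")
    }
    emg_record(dat[[1]], fs, label = label, units = units)
  } else {
    stop("unrecognized CSV layout in ", path,
         ": expected header 'time_s,amplitude' or a single column")
  }
}

#' Write a record to CSV
#'
#' @param record An [emg_record()].
#' @param path Output path; columns `time_s`, `amplitude`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "emg_record"))
  n <- length(record$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / record$sampling_rate,
               amplitude = record$samples),
    path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth cycle timing to CSV
#'
#' @param truth Data frame with `cycle_index`, `onset_s`, `offset_s`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Read ground-truth or scorer annotations from CSV
#'
#' @param path CSV with at least `onset_s` and `offset_s` columns.
#' @param scorer_id Optional scorer identifier; when given, an
#'   [annotation_set()] is returned instead of a data frame.
#' @return A data frame, or an [annotation_set()] when `scorer_id` is set.
#' @export
read_annotations <- function(path, scorer_id = NULL) {
  dat <- utils::read.csv(path)
  if (!all(c("onset_s", "offset_s") %in% names(dat))) {
    stop("annotation file must contain onset_s and offset_s columns")
  }
  if (is.null(scorer_id)) return(dat)
  annotation_set(scorer_id, dat$onset_s, dat$offset_s)
}

#' Write detected cycles to CSV with a JSON provenance mirror
#'
#' Writes one row per event with `cycle_index`, `marker_s`, `onset_s`,
#' `offset_s`, `onset_corrected_s`, `offset_corrected_s` and the
#' semicolon-joined `flags`. A JSON file with the same stem carries the
#' table together with configuration/provenance metadata.
#'
#' @param cycles Event data frame.
#' @param path Output CSV path.
#' @param meta Named list of provenance metadata stored in the JSON
#'   mirror.
#' @return The CSV path, invisibly.
#' @export
write_cycles <- function(cycles, path, meta = list()) {
  cols <- c("marker_s", "onset_s", "offset_s",
            "onset_corrected_s", "offset_corrected_s", "flags")
  out <- data.frame(cycle_index = seq_len(nrow(cycles)))
  for (cl in cols) {
    out[[cl]] <- if (cl %in% names(cycles)) cycles[[cl]] else NA_real_
  }
  if (!nrow(cycles)) out <- out[0, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(meta = c(meta, list(package_version =
                               as.character(utils::packageVersion("emgdi")))),
         cycles = out),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read detected cycles back from CSV
#'
#' @param path CSV written by [write_cycles()].
#' @return The event data frame.
#' @export
read_cycles <- function(path) {
  dat <- utils::read.csv(path, colClasses = c(flags = "character"))
  dat$flags[is.na(dat$flags)] <- ""
  dat
}
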