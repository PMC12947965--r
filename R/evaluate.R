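#' Construct a scorer annotation set
#'
#' @param scorer_id Identifier of the scorer.
#' @param onset_s,offset_s Numeric vectors of interval bounds in seconds;
#'   intervals must be sorted and non-overlapping.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(scorer_id, onset_s, offset_s) {
  if (length(onset_s) != length(offset_s)) {
    stop("onset and offset vectors must have equal length")
  }
  if (any(offset_s <= onset_s)) stop("each offset must follow its onset")
  ord <- order(onset_s)
  onset_s <- onset_s[ord]
  offset_s <- offset_s[ord]
  if (length(onset_s) > 1L && any(onset_s[-1] < offset_s[-length(offset_s)])) {
    stop("annotated intervals must not overlap")
  }
  structure(list(scorer_id = scorer_id,
                 intervals = data.frame(onset_s = onset_s,
                                        offset_s = offset_s)),
            class = "annotation_set")
}

#' Pair two scorers' annotations into reliable events
#'
#' Intervals from the two scorers that overlap in time are considered to
#' mark the same inspiratory effort. Only uniquely matched pairs are kept:
#' an interval overlapping more than one counterpart has no unique match
#' and is excluded, as are intervals seen by one scorer only. Within each
#' pair the onset is reliable when the scorers differ by strictly less
#' than 150 ms, and likewise (independently) for the offset; the reference
#' time for a reliable marker is the arithmetic mean of the two expert
#' markers. The result is symmetric in the two scorers.
#'
#' @param a,b [annotation_set()]s.
#' @param tolerance Marker agreement tolerance in seconds.
#' @return A `scorer_reference`: list with `reliable` (data frame with the
#'   paired intervals, per-marker reliability and reference times, plus
#'   the event span `lo_s`/`hi_s` used for overlap matching) and
#'   `excluded` (intervals from either scorer without a unique match).
#' @export
pair_scorers <- function(a, b, tolerance = 0.150) {
  stopifnot(inherits(a, "annotation_set"), inherits(b, "annotation_set"))
  ia <- a$intervals
  ib <- b$intervals
  na <- nrow(ia)
  nb <- nrow(ib)
  # overlap counts; unique pairs are kept
  overlaps <- function(on1, off1, on2, off2) {
    outer(seq_along(on1), seq_along(on2), function(i, j) {
      pmin(off1[i], off2[j]) - pmax(on1[i], on2[j])
    }) > 0
  }
  if (na && nb) {
    ov <- overlaps(ia$onset_s, ia$offset_s, ib$onset_s, ib$offset_s)
    cnt_a <- rowSums(ov)
    cnt_b <- colSums(ov)
    pairs <- which(ov, arr.ind = TRUE)
    unique_pair <- cnt_a[pairs[, 1]] == 1L & cnt_b[pairs[, 2]] == 1L
    pairs <- pairs[unique_pair, , drop = FALSE]
  } else {
    pairs <- matrix(integer(0), ncol = 2)
    cnt_a <- rep(0L, na)
    cnt_b <- rep(0L, nb)
  }
  if (nrow(pairs)) {
    pairs <- pairs[order(ia$onset_s[pairs[, 1]]), , drop = FALSE]
    d_on <- ia$onset_s[pairs[, 1]] - ib$onset_s[pairs[, 2]]
    d_off <- ia$offset_s[pairs[, 1]] - ib$offset_s[pairs[, 2]]
    reliable <- data.frame(
      a_onset_s = ia$onset_s[pairs[, 1]],
      a_offset_s = ia$offset_s[pairs[, 1]],
      b_onset_s = ib$onset_s[pairs[, 2]],
      b_offset_s = ib$offset_s[pairs[, 2]],
      onset_reliable = abs(d_on) < tolerance,
      offset_reliable = abs(d_off) < tolerance
    )
    reliable$ref_onset_s <- ifelse(reliable$onset_reliable,
                                   (reliable$a_onset_s + reliable$b_onset_s) / 2,
                                   NA_real_)
    reliable$ref_offset_s <- ifelse(reliable$offset_reliable,
                                    (reliable$a_offset_s + reliable$b_offset_s) / 2,
                                    NA_real_)
    reliable$lo_s <- pmin(reliable$a_onset_s, reliable$b_onset_s)
    reliable$hi_s <- pmax(reliable$a_offset_s, reliable$b_offset_s)
  } else {
    reliable <- data.frame(a_onset_s = numeric(0), a_offset_s = numeric(0),
                           b_onset_s = numeric(0), b_offset_s = numeric(0),
                           onset_reliable = logical(0),
                           offset_reliable = logical(0),
                           ref_onset_s = numeric(0), ref_offset_s = numeric(0),
                           lo_s = numeric(0), hi_s = numeric(0))
  }
  matched_a <- if (nrow(pairs)) pairs[, 1] else integer(0)
  matched_b <- if (nrow(pairs)) pairs[, 2] else integer(0)
  excluded <- rbind(
    if (na) data.frame(onset_s = ia$onset_s, offset_s = ia$offset_s,
                       scorer = a$scorer_id)[setdiff(seq_len(na), matched_a), ],
    if (nb) data.frame(onset_s = ib$onset_s, offset_s = ib$offset_s,
                       scorer = b$scorer_id)[setdiff(seq_len(nb), matched_b), ]
  )
  if (is.null(excluded)) {
    excluded <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                           scorer = character(0))
  }
  structure(list(reliable = reliable, excluded = excluded,
                 tolerance = tolerance),
            class = "scorer_reference")
}

#' Match automatic detections against the reliable-event reference
#'
#' A detection overlapping a reliable event is a true positive (each event
#' can be matched once; ties resolved greedily by overlap length). A
#' reliable event with no overlapping detection is a false negative. A
#' detection overlapping neither a reliable event nor one of the excluded
#' (unreliable) intervals is a false positive; detections touching only
#' unreliable intervals are ignored, since no trustworthy reference exists
#' there.
#'
#' @param detected Data frame of detected cycles with `onset_s` and
#'   `offset_s` (accepted cycles).
#' @param reference A `scorer_reference` from [pair_scorers()].
#' @return A `match_report`: list with `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `f1` and the TP index pairs (`pairs`).
#' @export
match_detections <- function(detected, reference) {
  stopifnot(inherits(reference, "scorer_reference"))
  rel <- reference$reliable
  pairs <- match_intervals(detected$onset_s, detected$offset_s,
                           rel$lo_s, rel$hi_s)
  tp <- nrow(pairs)
  fn <- nrow(rel) - tp
  unmatched <- setdiff(seq_len(nrow(detected)), pairs[, "a"])
  fp <- 0L
  if (length(unmatched) && nrow(reference$excluded)) {
    ex <- reference$excluded
    for (i in unmatched) {
      touches <- any(pmin(detected$offset_s[i], ex$offset_s) >
                       pmax(detected$onset_s[i], ex$onset_s))
      if (!touches) fp <- fp + 1L
    }
  } else {
    fp <- length(unmatched)
  }
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(se) && !is.na(pr) && se + pr > 0) {
    2 * se * pr / (se + pr)
  } else {
    NA_real_
  }
  structure(list(tp = tp, fp = fp, fn = fn, sensitivity = se,
                 precision = pr, f1 = f1, pairs = pairs),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> TP %d  FP %d  FN %d | Se %.3f  Pr %.3f  F1 %.3f\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$precision, x$f1))
  invisible(x)
}

#' Timing agreement between detections and the scorer reference
#'
#' For true-positive pairs whose reference marker is reliable, computes
#' the differences `d = detected - reference` and reports the mean
#' difference, the population standard deviation and the root mean square
#' error. With the population SD convention, `rmse^2 = md^2 + sd^2` holds
#' exactly.
#'
#' @param detected Data frame of detected cycles (with corrected columns
#'   used when `use_corrected = TRUE` and present).
#' @param reference A `scorer_reference`.
#' @param marker `"onset"` or `"offset"`.
#' @param use_corrected Use `onset_corrected_s`/`offset_corrected_s` when
#'   available.
#' @return A `timing_report`: list with `n`, `md`, `sd`, `rmse` (seconds)
#'   and `empty`.
#' @export
timing_metrics <- function(detected, reference,
                           marker = c("onset", "offset"),
                           use_corrected = FALSE) {
  marker <- match.arg(marker)
  rep_ <- match_detections(detected, reference)
  rel <- reference$reliable
  col <- if (use_corrected &&
             paste0(marker, "_corrected_s") %in% names(detected)) {
    paste0(marker, "_corrected_s")
  } else {
    paste0(marker, "_s")
  }
  ref_col <- paste0("ref_", marker, "_s")
  rel_col <- paste0(marker, "_reliable")
  pairs <- rep_$pairs
  if (nrow(pairs)) {
    ok <- rel[[rel_col]][pairs[, "b"]]
    d <- detected[[col]][pairs[, "a"]][ok] - rel[[ref_col]][pairs[, "b"]][ok]
  } else {
    d <- numeric(0)
  }
  if (!length(d)) {
    return(structure(list(n = 0L, md = NA_real_, sd = NA_real_,
                          rmse = NA_real_, empty = TRUE),
                     class = "timing_report"))
  }
  md <- mean(d)
  sdev <- sqrt(mean((d - md)^2))  # population convention
  structure(list(n = length(d), md = md, sd = sdev,
                 rmse = sqrt(mean(d^2)), empty = FALSE),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  if (x$empty) {
    cat("<timing_report> no reliable pairs\n")
  } else {
    cat(sprintf("<timing_report> n %d | MD %+.1f ms  SD %.1f ms  RMSE %.1f ms\n",
                x$n, 1000 * x$md, 1000 * x$sd, 1000 * x$rmse))
  }
  invisible(x)
}
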