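## Criterion-standard comparison against video-rated intervals, threshold
## sweeps, and per-activity summaries.
##
## Scoring is sample-wise on the elevation-trace time grid (the published
## quantities are time ratios, which sample-wise scoring converges to).
## Membership conventions: active-bout membership is closed [start, end];
## annotation-interval membership is half-open [start, end).

#' Classify samples as active or resting from a bout set
#'
#' Samples inside any active bout (closed interval) are `"active"`;
#' everything else -- resting bouts and edge slack -- is `"resting"`.
#'
#' @param bouts A `bout_set` from [segment_bouts()].
#' @param t Sample times in seconds.
#' @return Character vector of `"active"`/`"resting"`, one per sample.
#' @export
classify_samples <- function(bouts, t) {
  stopifnot(inherits(bouts, "bout_set"))
  lab <- rep("resting", length(t))
  act <- bouts[bouts$kind == "active", , drop = FALSE]
  for (i in seq_len(nrow(act)))
    lab[t >= act$start_s[i] & t <= act$end_s[i]] <- "active"
  lab
}

## Annotation labels resampled to a grid: "active" (propulsion or
## non_propulsion), "resting", or NA where no interval covers the sample.
annotation_labels_at <- function(truth, t) {
  lab <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(truth))) {
    sel <- t >= truth$start_s[i] & t < truth$end_s[i]
    lab[sel] <- if (truth$label[i] == "resting") "resting" else "active"
  }
  lab
}

#' Score predicted activity against annotated intervals
#'
#' Accuracy is the ratio of true-active plus true-resting time to total
#' time; sensitivity is true-active over total (annotated) active time;
#' specificity is true-resting over total (annotated) resting time. Samples
#' not covered by any annotation interval are excluded from every numerator
#' and denominator (with a message).
#'
#' @param pred Character vector of `"active"`/`"resting"` per sample, e.g.
#'   from [classify_samples()].
#' @param truth An [annotation_track()]; `propulsion` and `non_propulsion`
#'   both count as active.
#' @param t Sample times shared by `pred` and the annotation clock.
#' @return Object of class `validation_scores`: list with `accuracy`,
#'   `sensitivity`, `specificity`, `true_active_s`, `true_resting_s`,
#'   `total_s`, `n_excluded`.
#' @export
score_against_annotations <- function(pred, truth, t) {
  stopifnot(inherits(truth, "annotation_track"), length(pred) == length(t))
  truth_lab <- annotation_labels_at(truth, t)
  keep <- !is.na(truth_lab)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L)
    message(sprintf("score_against_annotations: %d sample(s) not covered by annotations excluded", n_excluded))
  pred <- pred[keep]; truth_lab <- truth_lab[keep]; tk <- t[keep]
  if (!length(tk)) stop("no annotated samples to score", call. = FALSE)
  dt <- if (length(t) >= 2L) stats::median(diff(t)) else 1
  ta <- sum(pred == "active" & truth_lab == "active") * dt
  tr <- sum(pred == "resting" & truth_lab == "resting") * dt
  total <- length(tk) * dt
  act_total <- sum(truth_lab == "active") * dt
  rest_total <- sum(truth_lab == "resting") * dt
  structure(list(
    accuracy = (ta + tr) / total,
    sensitivity = if (act_total > 0) ta / act_total else NA_real_,
    specificity = if (rest_total > 0) tr / rest_total else NA_real_,
    true_active_s = ta, true_resting_s = tr, total_s = total,
    n_excluded = n_excluded), class = "validation_scores")
}

#' Count detected cycles inside annotated intervals
#'
#' A cycle is attributed to an interval when its peak time lies inside it
#' (half-open `[start, end)`); the published stroke-count comparison uses
#' this to count propulsion strokes. The signed error fraction is
#' `(estimated - actual) / actual`: negative means underestimation.
#'
#' @param cycles A `cycle_set`.
#' @param truth An [annotation_track()].
#' @param label_filter Labels whose intervals are selected (default
#'   `"propulsion"`).
#' @param actual The criterion-standard count, or `NA`.
#' @return List with `estimated`, `actual`, `error_fraction` (`NA` when
#'   `actual` is 0 or missing).
#' @export
count_cycles_in_intervals <- function(cycles, truth,
                                      label_filter = "propulsion",
                                      actual = NA_integer_) {
  stopifnot(inherits(cycles, "cycle_set"), inherits(truth, "annotation_track"))
  sel <- truth[truth$label %in% label_filter, , drop = FALSE]
  est <- 0L
  for (i in seq_len(nrow(sel)))
    est <- est + sum(cycles$peak_s >= sel$start_s[i] & cycles$peak_s < sel$end_s[i])
  err <- if (is.na(actual) || actual == 0) NA_real_ else (est - actual) / actual
  list(estimated = est, actual = actual, error_fraction = err)
}

#' Sweep the movement threshold
#'
#' Runs cycle detection and bout segmentation at each threshold; when an
#' annotation track is supplied, also scores active/resting classification
#' against it.
#'
#' @param trace A smoothed [elevation_trace()].
#' @param thresholds Thresholds in degrees (default `c(5, 10, 15, 20)`).
#' @param truth Optional [annotation_track()].
#' @param idle_band_deg Anchoring band; capped below each threshold.
#' @param rest_gap_s Rest rule in seconds.
#' @return Data frame with one row per threshold: `threshold_deg`,
#'   `n_cycles`, `n_active_bouts`, `n_resting_bouts`, `total_active_s`,
#'   `total_resting_s`, and (with truth) `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
threshold_sweep <- function(trace, thresholds = c(5, 10, 15, 20), truth = NULL,
                            idle_band_deg = 2, rest_gap_s = 7) {
  stopifnot(inherits(trace, "elevation_trace"))
  thresholds <- as.numeric(thresholds)
  if (any(thresholds <= 0) || anyDuplicated(thresholds))
    stop("thresholds must be positive and distinct", call. = FALSE)
  rows <- lapply(thresholds, function(th) {
    band <- min(idle_band_deg, th / 2)
    cyc <- detect_cycles(trace, th, band)
    bouts <- segment_bouts(cyc, rest_gap_s, trace_span(trace))
    row <- data.frame(
      threshold_deg = th, n_cycles = nrow(cyc),
      n_active_bouts = sum(bouts$kind == "active"),
      n_resting_bouts = sum(bouts$kind == "resting"),
      total_active_s = sum(bouts$duration_s[bouts$kind == "active"]),
      total_resting_s = sum(bouts$duration_s[bouts$kind == "resting"]))
    if (!is.null(truth)) {
      sc <- score_against_annotations(classify_samples(bouts, trace$t),
                                      truth, trace$t)
      row$accuracy <- sc$accuracy
      row$sensitivity <- sc$sensitivity
      row$specificity <- sc$specificity
    }
    row
  })
  do.call(rbind, rows)
}

#' Per-activity (per-label) cycle summaries
#'
#' Groups detected cycles by annotated activity label (assignment by peak
#' time) and summarises per-cycle median and peak elevation; the shape of the
#' per-activity tables reported for in-home activities.
#'
#' @param cycles A `cycle_set`.
#' @param trace The [elevation_trace()] the cycles came from (unused beyond
#'   validation; per-cycle statistics are carried by the cycle set).
#' @param truth An [annotation_track()].
#' @return Data frame with one row per label present in `truth`:
#'   `label`, `duration_s` (total annotated time), `n_cycles`,
#'   `median_elev_{mean,sd,median,iqr}`, `peak_elev_{mean,sd,median,iqr}`
#'   (per-cycle statistics; `NA` for labels with zero cycles).
#' @export
per_interval_metrics <- function(cycles, trace, truth) {
  stopifnot(inherits(cycles, "cycle_set"), inherits(truth, "annotation_track"))
  labels <- unique(truth$label)
  rows <- lapply(labels, function(lb) {
    iv <- truth[truth$label == lb, , drop = FALSE]
    inside <- rep(FALSE, nrow(cycles))
    for (i in seq_len(nrow(iv)))
      inside <- inside | (cycles$peak_s >= iv$start_s[i] & cycles$peak_s < iv$end_s[i])
    cc <- cycles[inside, , drop = FALSE]
    med <- mmsi(cc$median_elev_deg); pk <- mmsi(cc$peak_elev_deg)
    data.frame(label = lb, duration_s = sum(iv$end_s - iv$start_s),
               n_cycles = nrow(cc),
               median_elev_mean = med$mean, median_elev_sd = med$sd,
               median_elev_median = med$median, median_elev_iqr = med$iqr,
               peak_elev_mean = pk$mean, peak_elev_sd = pk$sd,
               peak_elev_median = pk$median, peak_elev_iqr = pk$iqr,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(), duration_s = numeric(), n_cycles = integer(),
               median_elev_mean = numeric(), median_elev_sd = numeric(),
               median_elev_median = numeric(), median_elev_iqr = numeric(),
               peak_elev_mean = numeric(), peak_elev_sd = numeric(),
               peak_elev_median = numeric(), peak_elev_iqr = numeric())
  rownames(out) <- NULL
  out
}
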