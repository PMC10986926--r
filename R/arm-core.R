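## The ARM algorithm proper: turning points, amplitude-threshold movement
## cycles, active/resting bout segmentation, and the exposure metric set.

#' Extract alternating turning points of an elevation trace
#'
#' Returns the strictly alternating local minima/maxima of the sampled angle,
#' including both endpoints. Plateaus (runs of equal values) are collapsed to
#' their first sample.
#'
#' @param trace An [elevation_trace()] (or any list with `t` and `phi_deg`).
#' @return Data frame with columns `index` (into the trace), `t`, `value`,
#'   and `kind` (`"min"`/`"max"`). A constant trace yields a single row with
#'   `kind = NA`.
#' @export
extract_turning_points <- function(trace) {
  phi <- trace$phi_deg
  n <- length(phi)
  if (n < 2L)
    return(data.frame(index = seq_len(n), t = trace$t[seq_len(n)],
                      value = phi[seq_len(n)],
                      kind = rep(NA_character_, n)))
  ## collapse plateaus: keep the first sample of each run of equal values
  keep <- c(TRUE, diff(phi) != 0)
  idx <- which(keep)
  v <- phi[idx]
  if (length(idx) == 1L)   # constant trace
    return(data.frame(index = 1L, t = trace$t[1], value = phi[1],
                      kind = NA_character_))
  d <- diff(v)             # all non-zero by construction
  turn <- which(d[-1] * d[-length(d)] < 0) + 1L  # interior sign changes
  sel <- c(1L, turn, length(idx))
  kinds <- character(length(sel))
  kinds[1] <- if (d[1] > 0) "min" else "max"
  if (length(sel) > 1L)
    for (j in 2:length(sel)) kinds[j] <- if (kinds[j - 1] == "min") "max" else "min"
  data.frame(index = idx[sel], t = trace$t[idx[sel]], value = v[sel],
             kind = kinds, stringsAsFactors = FALSE)
}

## Iteratively prune the alternating extrema series: while the smallest
## adjacent range is below the threshold, delete that pair (leftmost on
## ties); a sub-threshold pair that includes the first or last extremum drops
## only that endpoint. Returns the surviving row indices of `tp`.
prune_extrema <- function(values, threshold_deg) {
  alive <- seq_along(values)
  repeat {
    if (length(alive) < 2L) break
    rng <- abs(diff(values[alive]))
    i <- which.min(rng)                 # leftmost minimal pair
    if (rng[i] >= threshold_deg) break
    if (i == 1L) {
      alive <- alive[-1L]               # endpoint dropped singly
    } else if (i == length(alive) - 1L) {
      alive <- alive[-length(alive)]
    } else {
      alive <- alive[-c(i, i + 1L)]
    }
  }
  alive
}

#' Detect movement cycles in an elevation trace
#'
#' A movement cycle is an arm elevation of at least `threshold_deg` followed
#' by a lowering of at least `threshold_deg`; sub-threshold motion between
#' those two events is "idle" and belongs to the cycle. Detection operates on
#' the alternating turning-point series: sub-threshold adjacent extremum
#' pairs are pruned (smallest range first, leftmost on ties; series endpoints
#' dropped singly), every interior surviving maximum defines one cycle, and
#' cycle boundaries are anchored in the raw trace at the last/first time the
#' angle is within `idle_band_deg` of the neighbouring valley value (and at
#' least `threshold_deg` below the surviving peak, which guarantees
#' `rise_deg` and `fall_deg` >= `threshold_deg`).
#'
#' An elevation at the end of the recording with no subsequent lowering (or
#' vice versa) is not a cycle. An empty or constant trace yields an empty
#' cycle set.
#'
#' @param trace A smoothed [elevation_trace()].
#' @param threshold_deg Movement threshold in degrees (default 10).
#' @param idle_band_deg Valley anchoring band in degrees; must be positive
#'   and below `threshold_deg` (default 2).
#' @return An object of class `cycle_set`: a data frame with columns
#'   `start_s`, `peak_s`, `end_s`, `rise_deg`, `fall_deg`, `peak_elev_deg`,
#'   `median_elev_deg`, plus attributes `threshold_deg` and `trace_span_s`.
#' @export
detect_cycles <- function(trace, threshold_deg = 10, idle_band_deg = 2) {
  stopifnot(inherits(trace, "elevation_trace"))
  if (!(idle_band_deg > 0 && idle_band_deg < threshold_deg))
    stop("must have 0 < idle_band_deg < threshold_deg", call. = FALSE)
  empty <- cycle_set(data.frame(start_s = numeric(), peak_s = numeric(),
                                end_s = numeric(), rise_deg = numeric(),
                                fall_deg = numeric(), peak_elev_deg = numeric(),
                                median_elev_deg = numeric()),
                     threshold_deg, trace_span(trace))
  if (length(trace$t) < 3L) return(empty)
  tp <- extract_turning_points(trace)
  if (nrow(tp) < 3L || anyNA(tp$kind)) return(empty)
  alive <- prune_extrema(tp$value, threshold_deg)
  if (length(alive) < 3L) return(empty)
  kept <- tp[alive, , drop = FALSE]
  phi <- trace$phi_deg
  rows <- vector("list", nrow(kept))
  nr <- 0L
  for (j in seq_len(nrow(kept))) {
    if (kept$kind[j] != "max") next
    if (j == 1L || j == nrow(kept)) next   # endpoint maxima lack one event
    peak_val <- kept$value[j]
    lo <- kept[j - 1L, ]; hi <- kept[j + 1L, ]
    start_lim <- min(lo$value + idle_band_deg, peak_val - threshold_deg)
    end_lim <- min(hi$value + idle_band_deg, peak_val - threshold_deg)
    sw <- lo$index:kept$index[j]
    ew <- kept$index[j]:hi$index
    si <- sw[max(which(phi[sw] <= start_lim))]
    ei <- ew[min(which(phi[ew] <= end_lim))]
    seg <- phi[si:ei]
    pk <- si + which.max(seg) - 1L
    nr <- nr + 1L
    rows[[nr]] <- data.frame(
      start_s = trace$t[si], peak_s = trace$t[pk], end_s = trace$t[ei],
      rise_deg = max(seg) - phi[si], fall_deg = max(seg) - phi[ei],
      peak_elev_deg = max(seg), median_elev_deg = stats::median(seg))
  }
  if (nr == 0L) return(empty)
  cycle_set(do.call(rbind, rows[seq_len(nr)]), threshold_deg, trace_span(trace))
}

trace_span <- function(trace) {
  if (length(trace$t) < 2L) 0 else trace$t[length(trace$t)] - trace$t[1]
}

#' Construct a cycle set
#'
#' @param cycles Data frame of per-cycle kinematics (see [detect_cycles()]).
#' @param threshold_deg Movement threshold the cycles were detected at.
#' @param span_s Recording span in seconds.
#' @return Object of class `cycle_set`.
#' @export
cycle_set <- function(cycles, threshold_deg, span_s = NA_real_) {
  stopifnot(is.data.frame(cycles))
  if (nrow(cycles)) {
    if (any(cycles$start_s >= cycles$peak_s) || any(cycles$peak_s >= cycles$end_s))
      stop("cycles must satisfy start_s < peak_s < end_s", call. = FALSE)
    if (nrow(cycles) > 1L &&
        any(cycles$start_s[-1] < cycles$end_s[-nrow(cycles)] - 1e-9))
      stop("cycles must be non-overlapping and time-ordered", call. = FALSE)
  }
  rownames(cycles) <- NULL
  structure(cycles, threshold_deg = threshold_deg, trace_span_s = span_s,
            class = c("cycle_set", "data.frame"))
}

#' Segment movement cycles into active and resting bouts
#'
#' Consecutive cycles whose no-activity gap (next start minus previous end)
#' is at most `rest_gap_s` share an active bout; a strictly larger gap closes
#' the bout and becomes one resting bout spanning the full gap. Cycle-free
#' time at the recording edges becomes a resting bout when strictly longer
#' than `rest_gap_s`, otherwise it is lead/trail slack.
#'
#' @param cycles A `cycle_set` from [detect_cycles()].
#' @param rest_gap_s Rest rule in seconds (default 7; only gaps strictly
#'   greater split bouts).
#' @param recording_span_s Total recording span; defaults to the span stored
#'   in the cycle set.
#' @param trace Optional [elevation_trace()]; when supplied, each active
#'   bout's `median_elev_deg` and `peak_elev_deg` are computed over its full
#'   span (including intra-bout idle time).
#' @return Object of class `bout_set`: data frame with columns `kind`
#'   (`"active"`/`"resting"`), `start_s`, `end_s`, `duration_s`, `n_cycles`,
#'   `median_elev_deg`, `peak_elev_deg`; attributes `recording_span_s`,
#'   `lead_slack_s`, `trail_slack_s`, `rest_gap_s`.
#' @export
segment_bouts <- function(cycles, rest_gap_s = 7, recording_span_s = NULL,
                          trace = NULL) {
  stopifnot(inherits(cycles, "cycle_set"))
  if (is.null(recording_span_s))
    recording_span_s <- attr(cycles, "trace_span_s")
  if (is.null(recording_span_s) || !is.finite(recording_span_s))
    stop("recording_span_s required", call. = FALSE)
  t0 <- 0
  t1 <- recording_span_s
  bouts <- list()
  lead_slack <- 0; trail_slack <- 0
  add <- function(kind, s, e, n_cyc = NA_integer_) {
    bouts[[length(bouts) + 1L]] <<- data.frame(
      kind = kind, start_s = s, end_s = e, duration_s = e - s,
      n_cycles = n_cyc, median_elev_deg = NA_real_, peak_elev_deg = NA_real_)
  }
  if (nrow(cycles) == 0L) {
    if (t1 - t0 > rest_gap_s) add("resting", t0, t1)
    else lead_slack <- t1 - t0
  } else {
    gaps <- if (nrow(cycles) > 1L)
      cycles$start_s[-1] - cycles$end_s[-nrow(cycles)] else numeric()
    grp <- cumsum(c(1L, as.integer(gaps > rest_gap_s)))
    ## leading edge
    lead <- cycles$start_s[1] - t0
    if (lead > rest_gap_s) add("resting", t0, cycles$start_s[1])
    else lead_slack <- lead
    for (g in unique(grp)) {
      sel <- which(grp == g)
      s <- cycles$start_s[sel[1]]; e <- cycles$end_s[sel[length(sel)]]
      add("active", s, e, length(sel))
      nxt <- which(grp == g + 1L)
      if (length(nxt)) add("resting", e, cycles$start_s[nxt[1]])
    }
    trail <- t1 - cycles$end_s[nrow(cycles)]
    if (trail > rest_gap_s) add("resting", cycles$end_s[nrow(cycles)], t1)
    else trail_slack <- trail
  }
  df <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(kind = character(), start_s = numeric(), end_s = numeric(),
               duration_s = numeric(), n_cycles = integer(),
               median_elev_deg = numeric(), peak_elev_deg = numeric())
  if (!is.null(trace) && nrow(df)) {
    act <- which(df$kind == "active")
    for (i in act) {
      sel <- trace$t >= df$start_s[i] - 1e-9 & trace$t <= df$end_s[i] + 1e-9
      if (any(sel)) {
        df$median_elev_deg[i] <- stats::median(trace$phi_deg[sel])
        df$peak_elev_deg[i] <- max(trace$phi_deg[sel])
      }
    }
  }
  rownames(df) <- NULL
  structure(df, recording_span_s = recording_span_s,
            lead_slack_s = lead_slack, trail_slack_s = trail_slack,
            rest_gap_s = rest_gap_s,
            class = c("bout_set", "data.frame"))
}

#' Compute the exposure metric report
#'
#' The metric set: counts and total durations of resting and active bouts;
#' per-bout duration, cycles per bout, and per-bout median and peak humeral
#' elevation, each summarised as (mean, sd, median, iqr). The four activity
#' families are reported twice: over all active bouts (`all_bouts`) and over
#' active bouts strictly longer than `long_bout_s` (`bouts_gt_long`).
#'
#' @param bouts A `bout_set` from [segment_bouts()].
#' @param trace Optional [elevation_trace()] used to (re)compute per-bout
#'   median/peak elevation over each bout's full span.
#' @param long_bout_s Long-bout cutoff in seconds (default 10, strict).
#' @return Object of class `metrics_report` (nested list; see
#'   [write_metrics_report()] for the serialized schema).
#' @export
compute_metrics <- function(bouts, trace = NULL, long_bout_s = 10) {
  stopifnot(inherits(bouts, "bout_set"))
  df <- as.data.frame(bouts)
  if (!is.null(trace) && nrow(df)) {
    act <- which(df$kind == "active")
    for (i in act) {
      sel <- trace$t >= df$start_s[i] - 1e-9 & trace$t <= df$end_s[i] + 1e-9
      if (any(sel)) {
        df$median_elev_deg[i] <- stats::median(trace$phi_deg[sel])
        df$peak_elev_deg[i] <- max(trace$phi_deg[sel])
      }
    }
  }
  rest <- df[df$kind == "resting", , drop = FALSE]
  act <- df[df$kind == "active", , drop = FALSE]
  group_stats <- function(a) {
    list(n_active_bouts = nrow(a),
         total_active_s = sum(a$duration_s),
         active_duration_s = mmsi(a$duration_s),
         cycles_per_bout = mmsi(as.numeric(a$n_cycles)),
         median_elevation_deg = mmsi(a$median_elev_deg),
         peak_elevation_deg = mmsi(a$peak_elev_deg))
  }
  rep <- list(
    n_resting_bouts = nrow(rest),
    total_resting_s = sum(rest$duration_s),
    resting_duration_s = mmsi(rest$duration_s),
    n_active_bouts = nrow(act),
    total_active_s = sum(act$duration_s),
    long_bout_s = long_bout_s,
    recording_span_s = attr(bouts, "recording_span_s"),
    all_bouts = group_stats(act),
    bouts_gt_long = group_stats(act[act$duration_s > long_bout_s, , drop = FALSE])
  )
  class(rep) <- "metrics_report"
  rep
}

## Flatten a metrics report into the fixed JSON key schema.
metrics_to_schema <- function(rep) {
  fam <- function(st, prefix, unit = "") {
    out <- list(st$mean, st$sd, st$median, st$iqr)
    names(out) <- paste0(prefix, c("mean", "sd", "median", "iqr"), unit)
    out
  }
  grp <- function(g) c(
    list(n_active_bouts = g$n_active_bouts, total_active_s = g$total_active_s),
    fam(g$active_duration_s, "active_duration_", "_s"),
    fam(g$cycles_per_bout, "cycles_per_bout_"),
    fam(g$median_elevation_deg, "median_elevation_deg_"),
    fam(g$peak_elevation_deg, "peak_elevation_deg_"))
  c(list(n_resting_bouts = rep$n_resting_bouts,
         total_resting_s = rep$total_resting_s),
    fam(rep$resting_duration_s, "resting_duration_", "_s"),
    list(n_active_bouts = rep$n_active_bouts,
         total_active_s = rep$total_active_s,
         long_bout_s = rep$long_bout_s,
         recording_span_s = rep$recording_span_s,
         all_bouts = grp(rep$all_bouts),
         bouts_gt_long = grp(rep$bouts_gt_long)))
}

#' Write a metrics report as JSON
#'
#' Fixed key schema: top-level resting-bout keys
#' (`n_resting_bouts`, `total_resting_s`, `resting_duration_{mean,sd,median,iqr}_s`),
#' top-level `n_active_bouts`/`total_active_s`, and two objects `all_bouts`
#' and `bouts_gt_long` each holding
#' `active_duration_{mean,sd,median,iqr}_s`, `cycles_per_bout_*`,
#' `median_elevation_deg_*`, `peak_elevation_deg_*` plus their own counts and
#' totals. Numbers are serialized at full precision; undefined statistics
#' (empty bout families) serialize as `null`.
#'
#' @param report A `metrics_report` from [compute_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(metrics_to_schema(report), path,
                       auto_unbox = TRUE, digits = I(17), null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a metrics report written by [write_metrics_report()]
#' @param path JSON path.
#' @return A `metrics_report`.
#' @export
read_metrics_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fam <- function(obj, prefix, unit = "") {
    g <- function(k) {
      v <- obj[[paste0(prefix, k, unit)]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }
    list(mean = g("mean"), sd = g("sd"), median = g("median"), iqr = g("iqr"))
  }
  grp <- function(obj) list(
    n_active_bouts = as.integer(obj$n_active_bouts),
    total_active_s = as.numeric(obj$total_active_s),
    active_duration_s = fam(obj, "active_duration_", "_s"),
    cycles_per_bout = fam(obj, "cycles_per_bout_"),
    median_elevation_deg = fam(obj, "median_elevation_deg_"),
    peak_elevation_deg = fam(obj, "peak_elevation_deg_"))
  rep <- list(
    n_resting_bouts = as.integer(x$n_resting_bouts),
    total_resting_s = as.numeric(x$total_resting_s),
    resting_duration_s = fam(x, "resting_duration_", "_s"),
    n_active_bouts = as.integer(x$n_active_bouts),
    total_active_s = as.numeric(x$total_active_s),
    long_bout_s = as.numeric(x$long_bout_s),
    recording_span_s = as.numeric(x$recording_span_s),
    all_bouts = grp(x$all_bouts),
    bouts_gt_long = grp(x$bouts_gt_long))
  class(rep) <- "metrics_report"
  rep
}

#' Full ARM analysis of an elevation trace
#'
#' Smooths the trace (unless `smooth = FALSE`), detects cycles, segments
#' bouts, and computes the metric report.
#'
#' @param trace An [elevation_trace()].
#' @param config An [arm_config()].
#' @param smooth Apply the zero-phase low-pass first? Default `TRUE`.
#' @return List with elements `trace` (smoothed), `cycles`, `bouts`,
#'   `metrics`.
#' @export
arm_analyze <- function(trace, config = arm_config(), smooth = TRUE) {
  stopifnot(inherits(trace, "elevation_trace"))
  sm <- if (smooth)
    smooth_trace(trace, config$lowpass_cutoff_hz, config$lowpass_order)
  else trace
  cyc <- detect_cycles(sm, config$movement_threshold_deg, config$idle_band_deg)
  bouts <- segment_bouts(cyc, config$rest_gap_s, trace_span(sm), trace = sm)
  metrics <- compute_metrics(bouts, trace = sm, long_bout_s = config$long_bout_s)
  list(trace = sm, cycles = cyc, bouts = bouts, metrics = metrics)
}
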