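## Bilateral (dominant vs non-dominant) comparison: descriptive summaries and
## paired Wilcoxon signed-rank tests.

#' Paired Wilcoxon signed-rank test
#'
#' Classical signed-rank test on paired differences `dominant - nondominant`
#' (or on differences supplied directly). Zero differences are dropped; tied
#' absolute differences receive mid-ranks. For `n_effective <= exact_limit`
#' the two-sided p-value is exact, from the full distribution of the
#' positive-rank sum over all sign assignments (computed by dynamic
#' programming over doubled ranks, equivalent to 2^n enumeration); above the
#' limit a normal approximation with tie correction and continuity
#' correction is used. Two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param dominant,nondominant Paired numeric vectors; or give `dominant` as
#'   a vector of differences and leave `nondominant` `NULL`.
#' @param exact_limit Largest `n_effective` for the exact branch (default 25).
#' @param method `"auto"` (default), `"exact"`, or `"normal"`.
#' @return Object of class `wilcoxon_result`: list with `statistic` (W, the
#'   positive-rank sum), `p_value`, `n`, `n_effective`, `method`,
#'   `degenerate` (all differences zero: p reported as 1).
#' @export
wilcoxon_signed_rank <- function(dominant, nondominant = NULL,
                                 exact_limit = 25,
                                 method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  d <- if (is.null(nondominant)) as.numeric(dominant)
       else as.numeric(dominant) - as.numeric(nondominant)
  d <- d[is.finite(d)]
  n <- length(d)
  if (n == 0L) stop("no finite paired differences", call. = FALSE)
  dz <- d[d != 0]
  n_eff <- length(dz)
  if (n_eff == 0L)
    return(structure(list(statistic = 0, p_value = 1, n = n, n_effective = 0L,
                          method = "degenerate", degenerate = TRUE),
                     class = "wilcoxon_result"))
  r <- rank(abs(dz))                  # mid-ranks for ties
  W <- sum(r[dz > 0])
  use_exact <- switch(method,
                      auto = n_eff <= exact_limit,
                      exact = TRUE,
                      normal = FALSE)
  if (use_exact) {
    p <- signed_rank_exact_p(r, W)
    meth <- "exact"
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    ties <- table(abs(dz))
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    meth <- "normal"
  }
  structure(list(statistic = W, p_value = p, n = n, n_effective = n_eff,
                 method = meth, degenerate = FALSE),
            class = "wilcoxon_result")
}

## Exact two-sided p for the positive-rank sum W given the rank vector.
## DP over doubled ranks (integers even with .5 mid-ranks): counts[k] is the
## number of sign assignments with doubled positive-rank sum k.
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)       # index k+1 <-> doubled sum k
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  w2 <- round(2 * W)
  p_le <- sum(counts[seq_len(w2 + 1L)]) / 2^length(r2)
  p_ge <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^length(r2)
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, p = %.5g (%s, n_eff = %d)\n",
              x$statistic, x$p_value, x$method, x$n_effective))
  invisible(x)
}

## Canonical metric ordering for bilateral reports (counts and totals first,
## then per-bout families, all-bouts before the long-bout stratum).
BILATERAL_METRIC_ORDER <- c(
  "n_resting_bouts", "total_resting_s", "resting_duration_mean_s",
  "n_active_bouts", "total_active_s", "active_duration_mean_s",
  "cycles_per_bout_mean", "median_elevation_deg_mean",
  "peak_elevation_deg_mean",
  "gt_long_n_active_bouts", "gt_long_total_active_s",
  "gt_long_active_duration_mean_s", "gt_long_cycles_per_bout_mean",
  "gt_long_median_elevation_deg_mean", "gt_long_peak_elevation_deg_mean")

#' Paired bilateral summary across participants
#'
#' One row per metric: per-side mean (SD) and median (Q1, Q3), plus the
#' paired Wilcoxon signed-rank test. Each participant must contribute at
#' most one pair per metric (average multi-day values per participant first;
#' see [average_by_participant()]). Pairs with a non-finite value are
#' excluded with a message. Metrics with fewer than 2 usable pairs are
#' summarised without a test and flagged.
#'
#' @param samples Data frame with columns `participant_id`, `metric`,
#'   `dominant`, `nondominant`.
#' @param metric_order Character vector fixing row order; metrics not listed
#'   are appended alphabetically. Defaults to the package's canonical order.
#' @return Data frame of class `bilateral_summary` with columns `metric`,
#'   `n_pairs`, `dom_mean`, `dom_sd`, `dom_median`, `dom_q1`, `dom_q3`,
#'   `nondom_*`, `W`, `p_value`, `n_effective`, `test_method`.
#' @export
bilateral_summary <- function(samples, metric_order = BILATERAL_METRIC_ORDER) {
  need <- c("participant_id", "metric", "dominant", "nondominant")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols))
    stop(sprintf("samples is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  dup <- duplicated(samples[c("participant_id", "metric")])
  if (any(dup))
    stop("each participant may contribute at most one pair per metric; average multi-day values first",
         call. = FALSE)
  mets <- unique(samples$metric)
  mets <- c(intersect(metric_order, mets), sort(setdiff(mets, metric_order)))
  rows <- lapply(mets, function(m) {
    s <- samples[samples$metric == m, , drop = FALSE]
    ok <- is.finite(s$dominant) & is.finite(s$nondominant)
    if (any(!ok))
      message(sprintf("bilateral_summary: metric '%s': %d pair(s) with non-finite values excluded",
                      m, sum(!ok)))
    s <- s[ok, , drop = FALSE]
    qd <- if (nrow(s)) quartiles(s$dominant) else rep(NA_real_, 3)
    qn <- if (nrow(s)) quartiles(s$nondominant) else rep(NA_real_, 3)
    out <- data.frame(
      metric = m, n_pairs = nrow(s),
      dom_mean = if (nrow(s)) mean(s$dominant) else NA_real_,
      dom_sd = if (nrow(s) > 1) stats::sd(s$dominant) else NA_real_,
      dom_median = qd[2], dom_q1 = qd[1], dom_q3 = qd[3],
      nondom_mean = if (nrow(s)) mean(s$nondominant) else NA_real_,
      nondom_sd = if (nrow(s) > 1) stats::sd(s$nondominant) else NA_real_,
      nondom_median = qn[2], nondom_q1 = qn[1], nondom_q3 = qn[3],
      W = NA_real_, p_value = NA_real_, n_effective = NA_integer_,
      test_method = "none", stringsAsFactors = FALSE)
    if (nrow(s) >= 2L) {
      wt <- wilcoxon_signed_rank(s$dominant, s$nondominant)
      out$W <- wt$statistic; out$p_value <- wt$p_value
      out$n_effective <- wt$n_effective; out$test_method <- wt$method
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bilateral_summary", "data.frame")
  out
}

#' Average multi-day metric values per participant
#'
#' Participants with several recording days are reduced to one value per
#' metric and side by averaging before testing.
#'
#' @param samples Data frame with columns `participant_id`, `metric`,
#'   `dominant`, `nondominant` (possibly several rows per participant and
#'   metric).
#' @return Data frame with one row per participant and metric.
#' @export
average_by_participant <- function(samples) {
  agg <- stats::aggregate(cbind(dominant, nondominant) ~ participant_id + metric,
                          data = samples, FUN = mean, na.action = stats::na.omit)
  agg[order(agg$metric, agg$participant_id), , drop = FALSE]
}

## Flatten a metrics_report into the named numeric vector used for bilateral
## comparison (canonical metric names).
metrics_to_vector <- function(rep) {
  stopifnot(inherits(rep, "metrics_report"))
  g <- rep$all_bouts; gl <- rep$bouts_gt_long
  c(n_resting_bouts = as.numeric(rep$n_resting_bouts),
    total_resting_s = rep$total_resting_s,
    resting_duration_mean_s = rep$resting_duration_s$mean,
    n_active_bouts = as.numeric(rep$n_active_bouts),
    total_active_s = rep$total_active_s,
    active_duration_mean_s = g$active_duration_s$mean,
    cycles_per_bout_mean = g$cycles_per_bout$mean,
    median_elevation_deg_mean = g$median_elevation_deg$mean,
    peak_elevation_deg_mean = g$peak_elevation_deg$mean,
    gt_long_n_active_bouts = as.numeric(gl$n_active_bouts),
    gt_long_total_active_s = gl$total_active_s,
    gt_long_active_duration_mean_s = gl$active_duration_s$mean,
    gt_long_cycles_per_bout_mean = gl$cycles_per_bout$mean,
    gt_long_median_elevation_deg_mean = gl$median_elevation_deg$mean,
    gt_long_peak_elevation_deg_mean = gl$peak_elevation_deg$mean)
}

#' Build paired samples from per-participant metric reports
#'
#' @param reports Named list: `reports[[participant]]$dominant` and
#'   `$nondominant` are `metrics_report` objects.
#' @return Data frame suitable for [bilateral_summary()].
#' @export
paired_samples_from_reports <- function(reports) {
  rows <- lapply(names(reports), function(pid) {
    dv <- metrics_to_vector(reports[[pid]]$dominant)
    nv <- metrics_to_vector(reports[[pid]]$nondominant)
    data.frame(participant_id = pid, metric = names(dv),
               dominant = as.numeric(dv), nondominant = as.numeric(nv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
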