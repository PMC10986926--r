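test_that("sample classification matches interval membership", {
  bouts <- segment_bouts(make_cycles(10, 15, 20, span = 30))
  lab <- classify_samples(bouts, 0:30)
  expect_equal(sum(lab == "active"), 11)   # closed [10, 20] at 1 Hz

  empty <- segment_bouts(make_cycles(numeric(), numeric(), numeric(), span = 30))
  expect_true(all(classify_samples(empty, 0:30) == "resting"))

  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(1:4, 1)
    s <- cumsum(runif(k, 8, 20)); e <- s + runif(k, 1, 6)
    span <- max(e) + 10
    bouts <- segment_bouts(make_cycles(s, s + 0.5, e, span = span))
    t <- seq(0, span, by = 0.5)
    got <- classify_samples(bouts, t)
    act <- bouts[bouts$kind == "active", ]
    want <- vapply(t, function(ti) {
      inside <- FALSE
      for (i in seq_len(nrow(act)))
        if (ti >= act$start_s[i] && ti <= act$end_s[i]) inside <- TRUE
      if (inside) "active" else "resting"
    }, character(1))
    expect_identical(got, want)
  }
})

test_that("validation scores reproduce hand-computed confusions", {
  t <- 0:99
  truth <- annotation_track(c(0, 50), c(50, 100), c("propulsion", "resting"))

  perfect <- ifelse(t < 50, "active", "resting")
  sc <- score_against_annotations(perfect, truth, t)
  expect_equal(sc$accuracy, 1); expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)

  pred <- ifelse(t < 40, "active", "resting")
  sc2 <- score_against_annotations(pred, truth, t)
  expect_equal(sc2$sensitivity, 0.8)
  expect_equal(sc2$specificity, 1.0)
  expect_equal(sc2$accuracy, 0.9)
  expect_equal(sc2$accuracy,
               (sc2$true_active_s + sc2$true_resting_s) / sc2$total_s,
               tolerance = 1e-9)

  lazy <- rep("resting", 100)
  sc3 <- score_against_annotations(lazy, truth, t)
  expect_equal(sc3$sensitivity, 0)
  expect_equal(sc3$specificity, 1)
  expect_equal(sc3$accuracy, 0.5)
})

test_that("swapping class roles swaps sensitivity and specificity", {
  t <- 0:99
  truth <- annotation_track(c(0, 50), c(50, 100), c("propulsion", "resting"))
  swapped <- annotation_track(c(0, 50), c(50, 100), c("resting", "propulsion"))
  pred <- ifelse(t < 40, "active", "resting")
  anti <- ifelse(pred == "active", "resting", "active")
  a <- score_against_annotations(pred, truth, t)
  b <- score_against_annotations(anti, swapped, t)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("uncovered samples are excluded with a message", {
  t <- 0:99
  truth <- annotation_track(0, 50, "propulsion")   # half the grid unlabelled
  pred <- rep("active", 100)
  expect_message(sc <- score_against_annotations(pred, truth, t), "excluded")
  expect_equal(sc$total_s, 50)
  expect_equal(sc$n_excluded, 50)
  expect_equal(sc$accuracy, 1)
})

test_that("stroke counts inside intervals and the signed error convention", {
  cyc <- make_cycles(seq(1, 41, 10), seq(2, 42, 10), seq(3, 43, 10), span = 60)
  truth <- annotation_track(0, 50, "propulsion")
  res <- count_cycles_in_intervals(cyc, truth, actual = 5)
  expect_equal(res$estimated, 5)
  expect_equal(res$error_fraction, 0)

  ## arithmetic of the published error cell: 1091 estimated vs 1116 actual
  expect_equal((1091 - 1116) / 1116, -0.0224, tolerance = 1e-3)

  res0 <- count_cycles_in_intervals(cyc, truth, actual = 0)
  expect_true(is.na(res0$error_fraction))

  for (seed in 1:15) {
    set.seed(seed)
    k <- sample(1:3, 1)
    s <- cumsum(runif(k, 5, 15)); e <- s + runif(k, 2, 8)
    truth <- annotation_track(s, e, rep("propulsion", k))
    got <- count_cycles_in_intervals(cyc, truth)$estimated
    want <- 0L
    for (p in cyc$peak_s)
      for (i in seq_len(k)) if (p >= s[i] && p < e[i]) want <- want + 1L
    expect_equal(got, want)
  }
})

test_that("threshold sweep reports all rows with monotone cycle counts", {
  ses <- generate_session(random_session_spec(11))
  tab <- threshold_sweep(ses$trace)
  expect_equal(tab$threshold_deg, c(5, 10, 15, 20))
  expect_true(all(diff(tab$n_cycles) <= 0))
  expect_false("accuracy" %in% names(tab))

  const <- elevation_trace(seq(0, 20, 0.1), rep(30, 201), 10)
  tab0 <- threshold_sweep(const)
  expect_true(all(tab0$n_cycles == 0))

  expect_error(threshold_sweep(ses$trace, c(5, 5, 10)), "distinct")
  expect_error(threshold_sweep(ses$trace, c(-5, 10)), "positive")
})

test_that("sweep cycle counts are non-increasing across 100 random sessions", {
  for (seed in 1:100) {
    ses <- generate_session(random_session_spec(seed))
    counts <- threshold_sweep(ses$trace, c(5, 10, 15, 20))$n_cycles
    expect_true(all(diff(counts) <= 0), info = paste("seed", seed))
  }
})

test_that("self-consistent annotations score perfectly up to the grid", {
  ses <- generate_session(random_session_spec(23))
  tr <- ses$trace
  cyc <- detect_cycles(tr, 10, 2)
  bouts <- segment_bouts(cyc, 7)
  act <- bouts[bouts$kind == "active", , drop = FALSE]
  span <- attr(bouts, "recording_span_s")
  ## stitch a full-coverage annotation from the ground-truth bouts
  edges <- sort(unique(c(0, act$start_s, act$end_s, span)))
  labs <- character(0); ss <- numeric(0); ee <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    mid <- (edges[i] + edges[i + 1]) / 2
    inside <- any(mid >= act$start_s & mid <= act$end_s)
    ss <- c(ss, edges[i]); ee <- c(ee, edges[i + 1])
    labs <- c(labs, if (inside) "propulsion" else "resting")
  }
  ann <- annotation_track(ss, ee, labs)
  sc <- score_against_annotations(classify_samples(bouts, tr$t), ann, tr$t)
  ## each bout boundary can flip at most ~2 grid samples (interval convention
  ## + grid snap); scale by the smaller class total
  slop <- 2 * (2 * nrow(act) + 2) / tr$fs_hz
  tol <- slop / min(sc$true_active_s, sc$true_resting_s)
  expect_gt(sc$accuracy, 1 - tol)
  expect_gt(sc$sensitivity, 1 - tol)
  expect_gt(sc$specificity, 1 - tol)
})

test_that("per-activity tables group cycles by peak membership", {
  cyc <- make_cycles(seq(1, 51, 10), seq(2, 52, 10), seq(3, 53, 10), span = 60)
  tr <- elevation_trace(seq(0, 60, 0.5), rep(15, 121), 2)

  whole <- annotation_track(0, 60, "propulsion")
  tab <- per_interval_metrics(cyc, tr, whole)
  expect_equal(tab$n_cycles, 6)
  expect_equal(tab$median_elev_mean, mean(cyc$median_elev_deg))
  expect_equal(tab$peak_elev_median, median(cyc$peak_elev_deg))

  split2 <- annotation_track(c(0, 40), c(40, 60),
                             c("propulsion", "non_propulsion"))
  tab2 <- per_interval_metrics(cyc, tr, split2)
  expect_equal(tab2$n_cycles[tab2$label == "propulsion"], 4)
  expect_equal(tab2$n_cycles[tab2$label == "non_propulsion"], 2)

  empty <- per_interval_metrics(cyc, tr, annotation_track())
  expect_equal(nrow(empty), 0)

  none <- annotation_track(55, 60, "resting")   # zero cycles under this label
  tab3 <- per_interval_metrics(cyc, tr, none)
  expect_equal(tab3$n_cycles, 0)
  expect_true(is.na(tab3$median_elev_mean))
})
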