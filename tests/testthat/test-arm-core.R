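## --- smoothing ------------------------------------------------------------

test_that("zero-phase low-pass preserves DC and the passband, kills noise", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  const <- elevation_trace(t, rep(42, length(t)), fs)
  expect_equal(smooth_trace(const)$phi_deg, rep(42, length(t)), tolerance = 1e-9)

  clean <- 40 + 30 * sin(2 * pi * 0.5 * t)
  sm <- smooth_trace(elevation_trace(t, clean, fs), cutoff_hz = 3, order = 4)
  mid <- 150:850   # away from the edges
  att <- 1 - diff(range(sm$phi_deg[mid])) / diff(range(clean[mid]))
  expect_lt(abs(att), 0.01)

  set.seed(3)
  noisy <- pmin(pmax(clean + 5 * sin(2 * pi * 20 * t) + rnorm(length(t), 0, 1), 0), 180)
  sm2 <- smooth_trace(elevation_trace(t, noisy, fs), cutoff_hz = 3, order = 4)
  expect_gt(cor(sm2$phi_deg[mid], clean[mid]), 0.999)
})

test_that("cutoff at or above Nyquist is a parameter error", {
  t <- seq(0, 5, by = 0.02)
  tr <- elevation_trace(t, rep(10, length(t)), 50)
  expect_error(smooth_trace(tr, cutoff_hz = 25), "Nyquist")
  expect_error(smooth_trace(tr, cutoff_hz = 30), "Nyquist")
})

## --- turning points -------------------------------------------------------

test_that("turning points: ramps, triangles, plateaus", {
  ramp <- elevation_trace(0:10, seq(0, 50, length.out = 11), 1)
  tp <- extract_turning_points(ramp)
  expect_equal(nrow(tp), 2)
  expect_equal(tp$kind, c("min", "max"))

  tri <- elevation_trace(0:10, c(seq(0, 50, 10), seq(40, 0, -10)), 1)
  tp2 <- extract_turning_points(tri)
  expect_equal(nrow(tp2), 3)
  expect_equal(tp2$kind, c("min", "max", "min"))
  expect_equal(tp2$value[2], 50)

  plateau <- elevation_trace(0:8, c(0, 10, 20, 20, 20, 10, 0, 0, 5), 1)
  tp3 <- extract_turning_points(plateau)
  expect_equal(tp3$index, c(1, 3, 7, 9))   # plateau collapsed to first sample
  expect_equal(tp3$kind, c("min", "max", "min", "max"))

  const <- elevation_trace(0:5, rep(20, 6), 1)
  expect_true(anyNA(extract_turning_points(const)$kind))
})

test_that("turning points match the brute-force scan on random traces", {
  for (seed in 1:100) {
    tr <- random_trace(seed)
    got <- extract_turning_points(tr)
    want <- oracle_turning_points(tr$phi_deg, tr$t)
    expect_equal(got$index, want$index, info = paste("seed", seed))
    expect_equal(got$kind, want$kind, info = paste("seed", seed))
  }
})

## --- cycle detection ------------------------------------------------------

test_that("constant and monotone traces contain no cycles", {
  const <- elevation_trace(seq(0, 10, 0.1), rep(20, 101), 10)
  expect_equal(nrow(detect_cycles(const, 10, 2)), 0)
  ramp <- elevation_trace(seq(0, 10, 0.1), seq(0, 50, length.out = 101), 10)
  expect_equal(nrow(detect_cycles(ramp, 10, 2)), 0)
})

test_that("a single triangle is one cycle with near-full rise and fall", {
  fs <- 50
  t <- seq(0, 4, by = 1 / fs)
  phi <- ifelse(t <= 2, 25 * t, 25 * (4 - t))
  cyc <- detect_cycles(elevation_trace(t, phi, fs), 10, 2)
  expect_equal(nrow(cyc), 1)
  expect_equal(cyc$peak_elev_deg, 50)
  ## boundaries anchor within the idle band of the valley (value 0 here)
  expect_gte(cyc$rise_deg, 50 - 2)
  expect_gte(cyc$fall_deg, 50 - 2)
  expect_true(cyc$start_s < cyc$peak_s && cyc$peak_s < cyc$end_s)
})

test_that("sub-threshold wiggles are idle, not cycles", {
  ## five 30 deg raises with three 5 deg wiggles interleaved
  fs <- 50
  bump <- function(amp, dur) {
    tt <- seq(0, dur, by = 1 / fs)[-1]
    amp / 2 * (1 - cos(2 * pi * tt / dur))
  }
  phi <- c(rep(0, fs))
  for (i in 1:5) {
    phi <- c(phi, bump(30, 2), rep(0, fs))
    if (i <= 3) phi <- c(phi, bump(5, 1), rep(0, fs))
  }
  tr <- elevation_trace((seq_along(phi) - 1) / fs, phi, fs)
  cyc <- detect_cycles(tr, 10, 2)
  expect_equal(nrow(cyc), 5)
  expect_true(all(cyc$rise_deg >= 10 & cyc$fall_deg >= 10))
})

test_that("cycle counts are non-increasing in the threshold", {
  for (seed in c(1, 7, 13, 29)) {
    ses <- generate_session(random_session_spec(seed, noise_sd = 1))
    sm <- smooth_trace(ses$trace)
    counts <- vapply(c(5, 10, 15, 20),
                     function(th) nrow(detect_cycles(sm, th, min(2, th / 2))),
                     numeric(1))
    expect_true(all(diff(counts) <= 0), info = paste("seed", seed))
  }
})

test_that("detect_cycles agrees exactly with the brute-force oracle", {
  for (seed in 1:150) {
    tr <- random_trace(seed, n = sample(50:300, 1))
    got <- detect_cycles(tr, 10, 2)
    want <- oracle_detect_cycles(tr, 10, 2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0, info = paste("seed", seed))
    } else {
      expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
      expect_equal(got$start_s, want$start_s, info = paste("seed", seed))
      expect_equal(got$peak_s, want$peak_s, info = paste("seed", seed))
      expect_equal(got$end_s, want$end_s, info = paste("seed", seed))
      expect_equal(got$rise_deg, want$rise_deg, info = paste("seed", seed))
    }
  }
})

test_that("every detected cycle rises and falls by at least the threshold", {
  for (seed in 101:140) {
    tr <- random_trace(seed, n = 250)
    for (th in c(5, 10, 15)) {
      cyc <- detect_cycles(tr, th, min(2, th / 2))
      if (nrow(cyc)) {
        expect_true(all(cyc$rise_deg >= th - 1e-9))
        expect_true(all(cyc$fall_deg >= th - 1e-9))
        expect_true(all(cyc$peak_elev_deg >= cyc$median_elev_deg))
        if (nrow(cyc) > 1)
          expect_true(all(cyc$start_s[-1] >= cyc$end_s[-nrow(cyc)] - 1e-9))
      }
    }
  }
})

## --- bout segmentation ----------------------------------------------------

test_that("bout segmentation follows the 7 s rule, strictly", {
  ## two cycles, 3 s gap: one active bout, edges too short to rest
  b1 <- segment_bouts(make_cycles(c(1, 6), c(2, 7), c(3, 8), span = 10))
  expect_equal(sum(b1$kind == "active"), 1)
  expect_equal(sum(b1$kind == "resting"), 0)
  expect_equal(b1$n_cycles[b1$kind == "active"], 2)

  ## two cycles, 8 s gap: two active bouts, one 8 s resting bout
  b2 <- segment_bouts(make_cycles(c(1, 11), c(2, 12), c(3, 13), span = 15))
  expect_equal(sum(b2$kind == "active"), 2)
  expect_equal(sum(b2$kind == "resting"), 1)
  expect_equal(b2$duration_s[b2$kind == "resting"], 8)

  ## gap of exactly 7.0 s does NOT split (only strictly greater than 7 does)
  b3 <- segment_bouts(make_cycles(c(1, 10), c(2, 11), c(3, 12), span = 14))
  expect_equal(sum(b3$kind == "active"), 1)

  ## programmed gaps (2, 9, 5, 12) s between 5 cycles of duration 2 s
  starts <- cumsum(c(0, 2 + c(2, 9, 5, 12)))
  b4 <- segment_bouts(make_cycles(starts, starts + 1, starts + 2, span = 40))
  act <- b4[b4$kind == "active", ]
  expect_equal(act$n_cycles, c(2, 2, 1))
  expect_equal(b4$duration_s[b4$kind == "resting"], c(9, 12))
})

test_that("edge time becomes rest only beyond the rest gap", {
  b <- segment_bouts(make_cycles(9, 10, 11, span = 30))
  expect_equal(b$kind, c("resting", "active", "resting"))
  expect_equal(attr(b, "lead_slack_s"), 0)
  expect_equal(attr(b, "trail_slack_s"), 0)

  b2 <- segment_bouts(make_cycles(3, 4, 5, span = 10))
  expect_equal(b2$kind, "active")
  expect_equal(attr(b2, "lead_slack_s"), 3)
  expect_equal(attr(b2, "trail_slack_s"), 5)
})

test_that("empty cycle sets partition into rest or slack by span", {
  long <- segment_bouts(make_cycles(numeric(), numeric(), numeric(), span = 60))
  expect_equal(long$kind, "resting")
  short <- segment_bouts(make_cycles(numeric(), numeric(), numeric(), span = 5))
  expect_equal(nrow(short), 0)
  expect_equal(attr(short, "lead_slack_s"), 5)
})

test_that("bout partition conserves the recording span on fuzzed sessions", {
  for (seed in 1:40) {
    ses <- generate_session(random_session_spec(seed, noise_sd = if (seed %% 2) 0 else 1))
    sm <- if (seed %% 2) ses$trace else smooth_trace(ses$trace)
    cyc <- detect_cycles(sm, 10, 2)
    bouts <- segment_bouts(cyc, 7)
    total <- sum(bouts$duration_s) + attr(bouts, "lead_slack_s") +
      attr(bouts, "trail_slack_s")
    dt <- 1 / ses$trace$fs_hz
    expect_lt(abs(total - attr(bouts, "recording_span_s")), dt + 1e-9)
    n_act <- sum(bouts$kind == "active"); n_rest <- sum(bouts$kind == "resting")
    expect_lte(abs(n_act - n_rest), 1)
    if (nrow(bouts) > 1)
      expect_true(all(bouts$kind[-1] != bouts$kind[-nrow(bouts)]))  # alternation
    expect_true(all(bouts$duration_s[bouts$kind == "resting"] > 7))
    expect_true(all(bouts$n_cycles[bouts$kind == "active"] >= 1))
    expect_lte(attr(bouts, "lead_slack_s"), 7 + 1e-9)
    expect_lte(attr(bouts, "trail_slack_s"), 7 + 1e-9)
  }
})

## --- metrics --------------------------------------------------------------

test_that("metric report arithmetic on hand-built bouts", {
  starts <- c(0, 15, 40)
  ends <- starts + c(5, 10, 20)
  cyc <- make_cycles(starts, starts + 2, ends, span = 70)
  bouts <- segment_bouts(cyc, 7)
  rep <- compute_metrics(bouts, long_bout_s = 10)
  expect_equal(rep$n_active_bouts, 3)
  expect_equal(rep$total_active_s, 35)
  expect_equal(rep$all_bouts$active_duration_s$mean, 35 / 3)
  expect_equal(rep$bouts_gt_long$n_active_bouts, 1)   # strict: only the 20 s bout
  expect_equal(rep$bouts_gt_long$total_active_s, 20)
  expect_lte(rep$bouts_gt_long$total_active_s, rep$all_bouts$total_active_s)
})

test_that("per-bout elevation statistics come from the full bout span", {
  fs <- 50
  t <- seq(0, 4, by = 1 / fs)
  phi <- ifelse(t <= 2, 25 * t, 25 * (4 - t))
  tr <- elevation_trace(t, phi, fs)
  cyc <- detect_cycles(tr, 10, 2)
  bouts <- segment_bouts(cyc, 7, trace = tr)
  rep <- compute_metrics(bouts, trace = tr, long_bout_s = 10)
  act <- bouts[bouts$kind == "active", ]
  expect_equal(act$peak_elev_deg, 50)
  sel <- t >= act$start_s & t <= act$end_s
  expect_equal(act$median_elev_deg, median(phi[sel]))
  expect_equal(rep$all_bouts$peak_elevation_deg$mean, 50)
})

test_that("empty input produces a zeroed report", {
  rep <- compute_metrics(segment_bouts(make_cycles(numeric(), numeric(),
                                                   numeric(), span = 3)))
  expect_equal(rep$n_active_bouts, 0)
  expect_equal(rep$total_active_s, 0)
  expect_true(is.na(rep$all_bouts$active_duration_s$mean))
})

test_that("arm_analyze runs the full chain with config defaults", {
  ses <- generate_session(random_session_spec(3, noise_sd = 1))
  res <- arm_analyze(ses$trace, arm_config())
  expect_s3_class(res$cycles, "cycle_set")
  expect_s3_class(res$bouts, "bout_set")
  expect_s3_class(res$metrics, "metrics_report")
  expect_equal(res$metrics$n_active_bouts, sum(res$bouts$kind == "active"))
})
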