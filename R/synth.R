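## Synthetic-data generator: programmable elevation-angle sessions with
## exact ground truth, and a forward IMU model that turns an elevation
## trajectory into raw accelerometer/gyroscope streams.
##
## Cycles are raised-cosine ramps (differentiable, bounded derivative, so
## gyroscope synthesis is well behaved). Ground-truth cycle boundaries are
## the idle-band crossing times of the ramps, in closed form -- the instants
## the detector is contractually required to find (see the methods
## vignette for why ramp endpoints would not round-trip).

#' Specify a synthetic session
#'
#' A session is: `lead_s` of baseline, then bouts of movement cycles
#' separated by rests, then `trail_s` of baseline. Each bout is a list with
#' `n_cycles`, `amplitude_deg` (scalar, per-cycle vector, or a range
#' `c(lo, hi)` sampled uniformly per cycle), `cycle_duration_s`,
#' `idle_at_top_s` (plateau at the peak, default 0) and `intra_bout_gap_s`
#' (baseline time between consecutive cycles, scalar or vector, each at most
#' `rest_gap_s`). `rests` are the baseline gaps between bouts, each strictly
#' greater than `rest_gap_s`.
#'
#' @param bouts List of bout specifications (see above).
#' @param rests Numeric vector of rest durations, length `length(bouts) - 1`.
#' @param fs_hz Sampling rate (default 50 Hz).
#' @param baseline_deg Baseline elevation, degrees (default 0: arm hanging,
#'   which is also the calibration posture assumed by the forward IMU model).
#' @param lead_s,trail_s Baseline padding at the edges (default 2 s each).
#' @param angle_noise_sd_deg Additive Gaussian angle noise, applied after
#'   ground truth is fixed (default 0).
#' @param truth_band_deg Idle band used for the closed-form ground-truth
#'   boundaries; match the analysis `idle_band_deg` (default 2).
#' @param rest_gap_s Rest rule the spec is validated against (default 7).
#' @param seed Integer seed; all randomness (amplitude draws, noise) flows
#'   from it.
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(bouts, rests = numeric(), fs_hz = 50,
                         baseline_deg = 0, lead_s = 2, trail_s = 2,
                         angle_noise_sd_deg = 0, truth_band_deg = 2,
                         rest_gap_s = 7, seed = NULL) {
  stopifnot(is.list(bouts))
  if (length(bouts) >= 1L && length(rests) != max(0L, length(bouts) - 1L))
    stop("rests must have length(bouts) - 1 entries", call. = FALSE)
  if (any(rests <= rest_gap_s))
    stop(sprintf("every rest duration must exceed rest_gap_s = %g s (field 'rests')",
                 rest_gap_s), call. = FALSE)
  for (i in seq_along(bouts)) {
    b <- bouts[[i]]
    if (is.null(b$n_cycles) || b$n_cycles < 1)
      stop(sprintf("bout %d: field 'n_cycles' must be >= 1", i), call. = FALSE)
    if (is.null(b$amplitude_deg) || any(b$amplitude_deg <= 0))
      stop(sprintf("bout %d: field 'amplitude_deg' must be positive", i), call. = FALSE)
    if (is.null(b$cycle_duration_s) || any(b$cycle_duration_s <= 0))
      stop(sprintf("bout %d: field 'cycle_duration_s' must be positive", i), call. = FALSE)
    if (!is.null(b$idle_at_top_s) && any(b$idle_at_top_s < 0))
      stop(sprintf("bout %d: field 'idle_at_top_s' must be >= 0", i), call. = FALSE)
    gaps <- b$intra_bout_gap_s
    if (!is.null(gaps) && any(gaps > rest_gap_s))
      stop(sprintf("bout %d: field 'intra_bout_gap_s' must be <= rest_gap_s = %g s",
                   i, rest_gap_s), call. = FALSE)
    if (!is.null(gaps) && any(gaps < 0))
      stop(sprintf("bout %d: field 'intra_bout_gap_s' must be >= 0", i), call. = FALSE)
  }
  structure(list(bouts = bouts, rests = as.numeric(rests),
                 fs_hz = as.numeric(fs_hz),
                 baseline_deg = as.numeric(baseline_deg),
                 lead_s = as.numeric(lead_s), trail_s = as.numeric(trail_s),
                 angle_noise_sd_deg = as.numeric(angle_noise_sd_deg),
                 truth_band_deg = as.numeric(truth_band_deg),
                 rest_gap_s = as.numeric(rest_gap_s),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "session_spec")
}

#' Propulsion-like bout preset (documentation aid)
#'
#' About 1 Hz cadence with 15-30 degree amplitudes, the regime of manual
#' wheelchair propulsion strokes.
#' @param n_cycles Number of strokes (default 10).
#' @return A bout specification list for [session_spec()].
#' @export
preset_propulsion_bout <- function(n_cycles = 10) {
  list(n_cycles = n_cycles, amplitude_deg = c(15, 30),
       cycle_duration_s = 1, idle_at_top_s = 0, intra_bout_gap_s = 0)
}

#' Reaching-like bout preset (documentation aid)
#'
#' Slow (0.2 Hz) large-amplitude (40-90 degree) reaches.
#' @param n_cycles Number of reaches (default 3).
#' @return A bout specification list for [session_spec()].
#' @export
preset_reaching_bout <- function(n_cycles = 3) {
  list(n_cycles = n_cycles, amplitude_deg = c(40, 90),
       cycle_duration_s = 5, idle_at_top_s = 0.5, intra_bout_gap_s = 2)
}

## Offset from a ramp endpoint to the band-crossing instant, closed form for
## the raised-cosine ramp phi = A/2 * (1 - cos(pi * tau / T_ramp)).
band_crossing_offset <- function(amplitude, t_ramp, band) {
  b <- min(band, amplitude / 2)   # degenerate guard; band << amplitude in use
  (t_ramp / pi) * acos(1 - 2 * b / amplitude)
}

#' Generate a synthetic session with exact ground truth
#'
#' Realizes a [session_spec()] as a sampled elevation trace plus ground-truth
#' cycles and bouts. Ground truth is fixed before noise is added, and
#' regenerating with the same spec (same seed) is bit-identical.
#'
#' @param spec A [session_spec()].
#' @return Object of class `synthetic_session`: list with `trace` (noisy),
#'   `clean_trace`, `truth_cycles` (a `cycle_set`), `truth_bouts`
#'   (a `bout_set`), and `spec`.
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  with_seed(spec$seed, {
    fs <- spec$fs_hz
    base <- spec$baseline_deg
    band <- spec$truth_band_deg
    ## resolve per-cycle amplitudes (a length-2 amplitude is a uniform range)
    cyc <- list()   # per-cycle: t0, T_up, idle, duration, amplitude
    cursor <- spec$lead_s
    for (j in seq_along(spec$bouts)) {
      b <- spec$bouts[[j]]
      nc <- as.integer(b$n_cycles)
      amp <- b$amplitude_deg
      amps <- if (length(amp) == nc) amp
              else if (length(amp) == 1L) rep(amp, nc)
              else if (length(amp) == 2L) stats::runif(nc, amp[1], amp[2])
              else stop(sprintf("bout %d: amplitude_deg must be scalar, range, or length n_cycles", j),
                        call. = FALSE)
      idle <- if (is.null(b$idle_at_top_s)) 0 else b$idle_at_top_s
      gaps <- b$intra_bout_gap_s
      gaps <- if (is.null(gaps)) rep(0, max(0L, nc - 1L))
              else if (length(gaps) == 1L) rep(gaps, max(0L, nc - 1L))
              else gaps
      dur <- b$cycle_duration_s
      durs <- if (length(dur) == 1L) rep(dur, nc) else dur
      for (k in seq_len(nc)) {
        D <- durs[k]
        t_up <- (D - idle) / 2
        if (t_up <= 0)
          stop(sprintf("bout %d: idle_at_top_s must be shorter than cycle_duration_s", j),
               call. = FALSE)
        cyc[[length(cyc) + 1L]] <- list(t0 = cursor, t_up = t_up, idle = idle,
                                        duration = D, amplitude = amps[k])
        cursor <- cursor + D
        if (k < nc) cursor <- cursor + gaps[k]
      }
      if (j < length(spec$bouts)) cursor <- cursor + spec$rests[j]
    }
    total_s <- cursor + spec$trail_s
    n <- floor(total_s * fs) + 1L
    t <- (seq_len(n) - 1L) / fs
    phi <- rep(base, n)
    for (cc in cyc) {
      i0 <- max(1L, ceiling(cc$t0 * fs) + 1L)
      i1 <- min(n, floor((cc$t0 + cc$duration) * fs) + 1L)
      if (i0 > i1) next
      tau <- t[i0:i1] - cc$t0
      A <- cc$amplitude; up <- cc$t_up; idle <- cc$idle; D <- cc$duration
      seg <- ifelse(tau <= up,
                    A / 2 * (1 - cos(pi * tau / up)),
                    ifelse(tau <= up + idle, A,
                           A / 2 * (1 - cos(pi * (D - tau) / up))))
      phi[i0:i1] <- base + seg
    }
    phi <- pmin(pmax(phi, 0), 180)
    clean <- elevation_trace(t, phi, fs)
    ## ground-truth cycles: band-crossing boundaries, closed form
    rows <- lapply(cyc, function(cc) {
      d_off <- band_crossing_offset(cc$amplitude, cc$t_up, band)
      s <- cc$t0 + d_off
      e <- cc$t0 + cc$duration - d_off
      pk <- cc$t0 + cc$t_up
      sel <- t >= s - 1e-9 & t <= e + 1e-9
      data.frame(start_s = s, peak_s = pk, end_s = e,
                 rise_deg = cc$amplitude - min(band, cc$amplitude / 2),
                 fall_deg = cc$amplitude - min(band, cc$amplitude / 2),
                 peak_elev_deg = if (any(sel)) max(phi[sel]) else base + cc$amplitude,
                 median_elev_deg = if (any(sel)) stats::median(phi[sel]) else NA_real_)
    })
    truth_cycles <- if (length(rows))
      cycle_set(do.call(rbind, rows), threshold_deg = NA_real_,
                span_s = t[n] - t[1])
    else cycle_set(data.frame(start_s = numeric(), peak_s = numeric(),
                              end_s = numeric(), rise_deg = numeric(),
                              fall_deg = numeric(), peak_elev_deg = numeric(),
                              median_elev_deg = numeric()),
                   threshold_deg = NA_real_, span_s = t[n] - t[1])
    truth_bouts <- segment_bouts(truth_cycles, spec$rest_gap_s,
                                 recording_span_s = t[n] - t[1], trace = clean)
    noisy <- if (spec$angle_noise_sd_deg > 0)
      elevation_trace(t, pmin(pmax(phi + stats::rnorm(n, 0, spec$angle_noise_sd_deg), 0), 180), fs)
    else clean
    structure(list(trace = noisy, clean_trace = clean,
                   truth_cycles = truth_cycles, truth_bouts = truth_bouts,
                   spec = spec),
              class = "synthetic_session")
  })
}

#' Forward IMU model: raw sensor streams from an elevation trajectory
#'
#' Models the humerus rotating in a fixed vertical plane: the sensor rotates
#' about a fixed horizontal axis (sensor x) by `phi(t)`; the gyroscope
#' measures `dphi/dt` (finite differences, rad/s) about that axis, and the
#' accelerometer measures gravity expressed in the sensor frame plus noise.
#' The sensor frame is chosen so that the calibration posture `phi = 0`
#' puts the humeral long axis (specific-force direction) on sensor z: a
#' hanging arm reads `(0, 0, 9.80665)` m/s^2.
#'
#' @param trace An [elevation_trace()]. For end-to-end round trips the trace
#'   should start with a static arm-hang (phi = 0) epoch usable as the
#'   calibration window.
#' @param accel_noise_sd_mps2 Accelerometer noise SD per axis (default 0).
#' @param gyro_noise_sd_rads Gyroscope noise SD per axis (default 0).
#' @param seed Integer seed for the noise.
#' @return An [imu_recording()].
#' @export
generate_imu_from_elevation <- function(trace, accel_noise_sd_mps2 = 0,
                                        gyro_noise_sd_rads = 0, seed = NULL) {
  stopifnot(inherits(trace, "elevation_trace"))
  with_seed(seed, {
    n <- length(trace$t)
    phi <- trace$phi_deg * pi / 180
    dphidt <- finite_gradient(phi, trace$t)
    accel <- cbind(0, GRAVITY_MPS2 * sin(phi), GRAVITY_MPS2 * cos(phi))
    gyro <- cbind(dphidt, 0, 0)
    if (accel_noise_sd_mps2 > 0)
      accel <- accel + matrix(stats::rnorm(3 * n, 0, accel_noise_sd_mps2), n, 3)
    if (gyro_noise_sd_rads > 0)
      gyro <- gyro + matrix(stats::rnorm(3 * n, 0, gyro_noise_sd_rads), n, 3)
    imu_recording(trace$t, accel, gyro, fs_hz = trace$fs_hz,
                  sensor_id = "synthetic")
  })
}

## Central-difference gradient with one-sided edges (numpy.gradient scheme).
finite_gradient <- function(y, x) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    g[i] <- (y[i + 1L] - y[i - 1L]) / (x[i + 1L] - x[i - 1L])
  }
  g
}

#' Write a session spec as JSON / read it back
#'
#' The schema mirrors the [session_spec()] arguments; used by the
#' `arm simulate` CLI.
#' @param spec A [session_spec()].
#' @param path JSON path.
#' @return `path` invisibly, or a `session_spec`.
#' @export
write_session_spec <- function(spec, path) {
  stopifnot(inherits(spec, "session_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_session_spec
#' @export
read_session_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bouts <- x$bouts
  if (is.data.frame(bouts)) bouts <- split(bouts, seq_len(nrow(bouts)))
  bouts <- lapply(bouts, function(b) {
    b <- as.list(b)
    for (f in c("n_cycles", "amplitude_deg", "cycle_duration_s",
                "idle_at_top_s", "intra_bout_gap_s"))
      if (!is.null(b[[f]])) b[[f]] <- unname(unlist(b[[f]]))
    b
  })
  session_spec(bouts = bouts,
               rests = if (is.null(x$rests)) numeric() else unlist(x$rests),
               fs_hz = x$fs_hz %||% 50,
               baseline_deg = x$baseline_deg %||% 0,
               lead_s = x$lead_s %||% 2, trail_s = x$trail_s %||% 2,
               angle_noise_sd_deg = x$angle_noise_sd_deg %||% 0,
               truth_band_deg = x$truth_band_deg %||% 2,
               rest_gap_s = x$rest_gap_s %||% 7,
               seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground truth as JSON (cycles + bouts), for the `arm simulate` CLI
#' @param session A `synthetic_session`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_session_truth <- function(session, path) {
  stopifnot(inherits(session, "synthetic_session"))
  jsonlite::write_json(
    list(cycles = as.data.frame(session$truth_cycles),
         bouts = as.data.frame(session$truth_bouts),
         recording_span_s = attr(session$truth_bouts, "recording_span_s"),
         lead_slack_s = attr(session$truth_bouts, "lead_slack_s"),
         trail_slack_s = attr(session$truth_bouts, "trail_slack_s")),
    path, auto_unbox = TRUE, digits = I(17), null = "null", na = "null",
    pretty = TRUE)
  invisible(path)
}
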