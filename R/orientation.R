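## Orientation estimation from accelerometer + gyroscope, no magnetometer.
##
## Quaternion convention (asserted in tests): scalar-first (w, x, y, z),
## right-handed, sensor-to-world. Heading (rotation about the world vertical)
## carries no accuracy contract: everything downstream depends only on the
## direction of gravity relative to the sensor, which is what the
## accelerometer correction keeps drift-free.

## --- minimal quaternion algebra (scalar-first) ---------------------------

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_normalize <- function(q) q / sqrt(sum(q * q))

## Unit quaternion for a rotation of |v| radians about axis v.
quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v * v))
  if (th < 1e-12) return(quat_normalize(c(1, v / 2)))
  c(cos(th / 2), sin(th / 2) * v / th)
}

## Rotate a 3-vector by unit quaternion q (sensor -> world for our q).
quat_rotate <- function(q, v) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  ## R(q) %*% v, expanded
  c((1 - 2 * (y * y + z * z)) * v[1] + 2 * (x * y - w * z) * v[2] + 2 * (x * z + w * y) * v[3],
    2 * (x * y + w * z) * v[1] + (1 - 2 * (x * x + z * z)) * v[2] + 2 * (y * z - w * x) * v[3],
    2 * (x * z - w * y) * v[1] + 2 * (y * z + w * x) * v[2] + (1 - 2 * (x * x + y * y)) * v[3])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

## Rotate rows of an n x 4 quaternion matrix applied to a single vector v:
## returns n x 3 matrix of R(q_i) %*% v. Vectorized over samples.
quat_rotate_many <- function(Q, v) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  cbind((1 - 2 * (y * y + z * z)) * v[1] + 2 * (x * y - w * z) * v[2] + 2 * (x * z + w * y) * v[3],
        2 * (x * y + w * z) * v[1] + (1 - 2 * (x * x + z * z)) * v[2] + 2 * (y * z - w * x) * v[3],
        2 * (x * z - w * y) * v[1] + 2 * (y * z + w * x) * v[2] + (1 - 2 * (x * x + y * y)) * v[3])
}

#' Construct an orientation trace
#'
#' @param t Sample times in seconds.
#' @param q n x 4 matrix of unit quaternions, scalar-first, sensor-to-world.
#' @return An object of class `orientation_trace`.
#' @export
orientation_trace <- function(t, q) {
  t <- as.numeric(t)
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("q must have 4 columns (w, x, y, z)", call. = FALSE)
  if (nrow(q) != length(t)) stop("q must have one row per time sample", call. = FALSE)
  nrm <- sqrt(rowSums(q * q))
  if (any(abs(nrm - 1) > 1e-9))
    stop("quaternions must be unit norm (|q| - 1 within 1e-9)", call. = FALSE)
  structure(list(t = t, q = q), class = "orientation_trace")
}

#' Estimate sensor orientation with a quaternion complementary filter
#'
#' Propagates orientation with the gyroscope (exact per-step quaternion
#' exponential) and corrects inclination toward the measured specific-force
#' direction with a small per-sample gain. The gravity-direction estimate is
#' drift-free; heading is not observable without a magnetometer and carries no
#' accuracy contract.
#'
#' @param rec An [imu_recording()].
#' @param gain Dimensionless per-sample accelerometer correction weight
#'   (default 0.02). Larger values trust the accelerometer more.
#' @return An [orientation_trace()].
#' @export
fuse_orientation <- function(rec, gain = 0.02) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$t)
  if (n < 1L) stop("empty recording", call. = FALSE)
  anorm <- sqrt(rowSums(rec$accel^2))
  if (all(anorm < 1e-9))
    stop("all accelerometer samples have zero norm; cannot estimate gravity",
         call. = FALSE)
  Q <- matrix(NA_real_, n, 4L)
  ## initialize from the first usable accel sample: minimal rotation taking
  ## the measured specific-force direction to the world up axis (0, 0, 1)
  i0 <- which(anorm >= 1e-9)[1]
  um <- rec$accel[i0, ] / anorm[i0]
  q <- quat_between(um, c(0, 0, 1))
  up_w <- c(0, 0, 1)
  skipped <- 0L
  for (i in seq_len(n)) {
    if (i > 1L) {
      dt <- rec$t[i] - rec$t[i - 1L]
      ## body-rate propagation, trapezoidal angular increment
      w_avg <- (rec$gyro[i, ] + rec$gyro[i - 1L, ]) / 2
      q <- quat_multiply(q, quat_from_rotvec(w_avg * dt))
    }
    if (anorm[i] >= 1e-9) {
      um <- rec$accel[i, ] / anorm[i]
      uw <- quat_rotate(q, um)           # measured up, world frame
      ax <- c(uw[2] * up_w[3] - uw[3] * up_w[2],
              uw[3] * up_w[1] - uw[1] * up_w[3],
              uw[1] * up_w[2] - uw[2] * up_w[1])   # uw x up_w
      s <- sqrt(sum(ax * ax))
      ang <- atan2(s, sum(uw * up_w))
      if (s > 1e-12 && ang > 0) {
        corr <- quat_from_rotvec(ax / s * (gain * ang))
        q <- quat_multiply(corr, q)      # world-frame correction
      }
    } else {
      skipped <- skipped + 1L            # gyro-only propagation this sample
    }
    q <- quat_normalize(q)
    Q[i, ] <- q
  }
  if (skipped > 0L)
    message(sprintf("fuse_orientation: %d zero-norm accelerometer sample(s); gyro-only propagation used", skipped))
  orientation_trace(rec$t, Q)
}

## Minimal rotation quaternion taking unit vector a to unit vector b.
quat_between <- function(a, b) {
  d <- sum(a * b)
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(ax * ax))
  if (s < 1e-12) {
    if (d > 0) return(c(1, 0, 0, 0))
    ## antiparallel: rotate pi about any axis orthogonal to a
    ortho <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * ortho[3] - a[3] * ortho[2],
            a[3] * ortho[1] - a[1] * ortho[3],
            a[1] * ortho[2] - a[2] * ortho[1])
    ax <- ax / sqrt(sum(ax * ax))
    return(c(0, ax))
  }
  quat_normalize(quat_from_rotvec(ax / s * atan2(s, d)))
}

#' Calibrate the humeral long axis from a static arm-hang posture
#'
#' During a quasi-static arm hang the accelerometer measures the specific
#' force (anti-gravity) direction in the sensor frame; its mean direction over
#' the window is taken as the humeral long-axis reference. The window must be
#' at least 1 s long and quasi-static (mean gyroscope magnitude below
#' 0.05 rad/s).
#'
#' @param rec An [imu_recording()].
#' @param window Numeric `c(start_s, end_s)` in recording time.
#' @return An object of class `calibration_model` with unit vector
#'   `long_axis_sensor`.
#' @export
calibrate_long_axis <- function(rec, window) {
  stopifnot(inherits(rec, "imu_recording"), length(window) == 2L)
  if (diff(window) < 1)
    stop(sprintf("calibration window must span at least 1 s (got %.3g s)",
                 diff(window)), call. = FALSE)
  idx <- which(rec$t >= window[1] & rec$t <= window[2])
  if (length(idx) < 2L)
    stop("calibration window contains fewer than 2 samples", call. = FALSE)
  gyro_mag <- mean(sqrt(rowSums(rec$gyro[idx, , drop = FALSE]^2)))
  if (gyro_mag >= 0.05)
    stop(sprintf("calibration window not quasi-static: mean gyro magnitude %.4g rad/s (limit 0.05)",
                 gyro_mag), call. = FALSE)
  v <- colMeans(rec$accel[idx, , drop = FALSE])
  nv <- sqrt(sum(v * v))
  if (nv < 1e-6)
    stop("mean specific force in calibration window is zero", call. = FALSE)
  structure(list(long_axis_sensor = v / nv, gyro_mag_rads = gyro_mag,
                 window = as.numeric(window)),
            class = "calibration_model")
}

#' Compute the humeral elevation angle trace
#'
#' The elevation angle is the angle between the humeral long axis and the
#' vertical: 0 degrees with the arm hanging (long axis along gravity), 180
#' degrees overhead. It depends only on the direction of gravity relative to
#' the segment and is therefore drift-free and heading-independent.
#'
#' @param orient An [orientation_trace()].
#' @param calib A `calibration_model` from [calibrate_long_axis()].
#' @return An [elevation_trace()].
#' @export
compute_elevation <- function(orient, calib) {
  stopifnot(inherits(orient, "orientation_trace"),
            inherits(calib, "calibration_model"))
  u <- calib$long_axis_sensor
  uw <- quat_rotate_many(orient$q, u)
  ## u is the specific-force (anti-gravity) reference: arm hanging maps it to
  ## world up, so cos(phi) is its world z component.
  cphi <- pmin(pmax(uw[, 3], -1), 1)
  elevation_trace(orient$t, acos(cphi) * 180 / pi)
}

#' Elevation trace straight from a raw IMU recording
#'
#' Convenience pipeline: [fuse_orientation()] then [calibrate_long_axis()] on
#' the given window, then [compute_elevation()].
#'
#' @inheritParams fuse_orientation
#' @inheritParams calibrate_long_axis
#' @return An [elevation_trace()].
#' @export
elevation_from_imu <- function(rec, window = c(0, 2), gain = 0.02) {
  orient <- fuse_orientation(rec, gain = gain)
  calib <- calibrate_long_axis(rec, window)
  compute_elevation(orient, calib)
}
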