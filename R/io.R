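## Core data containers and file boundary.
##
## All files are plain CSV/JSON: comma separator, UTF-8, '.' decimal, header
## row mandatory. Units are fixed at the boundary: seconds, m/s^2, rad/s,
## degrees. Times are recording-relative seconds starting at the first sample;
## annotations share this clock.

IMU_COLUMNS <- c("time_s", "ax_mps2", "ay_mps2", "az_mps2",
                 "gx_rads", "gy_rads", "gz_rads")
ANNOTATION_LABELS <- c("resting", "propulsion", "non_propulsion")

#' Construct an IMU recording
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param accel n x 3 matrix of specific force, m/s^2, sensor frame.
#' @param gyro n x 3 matrix of angular rate, rad/s, sensor frame.
#' @param fs_hz Nominal sampling rate in Hz; estimated from the median
#'   time step when missing.
#' @param sensor_id Text label for the sensor.
#' @param gap_action What to do when a time step deviates from 1/fs by more
#'   than half a sample period: `"error"` (default) or `"warn"`.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, accel, gyro, fs_hz = NULL, sensor_id = "sensor",
                          gap_action = c("error", "warn")) {
  gap_action <- match.arg(gap_action)
  t <- as.numeric(t)
  accel <- as_mat3(accel, "accel")
  gyro <- as_mat3(gyro, "gyro")
  n <- length(t)
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("accel and gyro must have one row per time sample", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(accel)) || !all(is.finite(gyro)))
    stop("IMU data must be finite", call. = FALSE)
  if (n >= 2L) {
    dt <- diff(t)
    bad <- which(dt <= 0)
    if (length(bad))
      stop(sprintf("time not strictly increasing at sample index %d", bad[1] + 1L),
           call. = FALSE)
  }
  if (is.null(fs_hz) || !is.finite(fs_hz)) {
    if (n < 2L) stop("cannot estimate fs from fewer than 2 samples", call. = FALSE)
    fs_hz <- 1 / stats::median(diff(t))
  }
  if (n >= 2L) {
    dev <- abs(diff(t) - 1 / fs_hz)
    worst <- max(dev)
    if (worst > 0.5 / fs_hz) {
      msg <- sprintf("timestamp gap at sample %d deviates from 1/fs by %.4g s (limit %.4g s)",
                     which.max(dev) + 1L, worst, 0.5 / fs_hz)
      if (gap_action == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  structure(list(sensor_id = as.character(sensor_id), t = t,
                 accel = accel, gyro = gyro, fs_hz = as.numeric(fs_hz)),
            class = "imu_recording")
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what), call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording '%s': %d samples, %.6g Hz, %.6g s>\n",
              x$sensor_id, length(x$t), x$fs_hz,
              if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

#' Read an IMU recording from CSV
#'
#' Expects the seven columns
#' `time_s,ax_mps2,ay_mps2,az_mps2,gx_rads,gy_rads,gz_rads`.
#'
#' @param path CSV file path.
#' @param fs_hint Nominal sampling rate in Hz; estimated from the median time
#'   step when absent.
#' @param sensor_id Label for the recording; defaults to the file name.
#' @inheritParams imu_recording
#' @return An [imu_recording()].
#' @export
read_imu_recording <- function(path, fs_hint = NULL, sensor_id = NULL,
                               gap_action = c("error", "warn")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(IMU_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("IMU CSV '%s' is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  imu_recording(
    t = df$time_s,
    accel = cbind(df$ax_mps2, df$ay_mps2, df$az_mps2),
    gyro = cbind(df$gx_rads, df$gy_rads, df$gz_rads),
    fs_hz = fs_hint,
    sensor_id = if (is.null(sensor_id)) basename(path) else sensor_id,
    gap_action = match.arg(gap_action)
  )
}

#' Write an IMU recording to CSV
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(time_s = rec$t,
                   ax_mps2 = rec$accel[, 1], ay_mps2 = rec$accel[, 2],
                   az_mps2 = rec$accel[, 3],
                   gx_rads = rec$gyro[, 1], gy_rads = rec$gyro[, 2],
                   gz_rads = rec$gyro[, 3])
  write_csv_full(df, path)
  invisible(path)
}

## write.csv with full double precision so read(write(x)) round trips exactly.
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Construct an annotation track
#'
#' Video-rated activity intervals used as the criterion standard. Labels are
#' restricted to `resting`, `propulsion`, `non_propulsion`. Intervals must be
#' non-overlapping; they are sorted by start time.
#'
#' @param start_s,end_s Interval boundaries in recording-relative seconds.
#' @param label Character vector of labels.
#' @return An object of class `annotation_track` (a data frame).
#' @export
annotation_track <- function(start_s = numeric(), end_s = numeric(),
                             label = character()) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   label = as.character(label), stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$label), ANNOTATION_LABELS)
  if (length(bad))
    stop(sprintf("unknown annotation label(s): %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(ANNOTATION_LABELS, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(df$start_s)) || any(!is.finite(df$end_s)))
    stop("annotation interval bounds must be finite", call. = FALSE)
  if (any(df$start_s >= df$end_s))
    stop("annotation intervals must satisfy start_s < end_s", call. = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) >= 2L) {
    ov <- which(df$start_s[-1] < df$end_s[-nrow(df)])
    if (length(ov))
      stop(sprintf("annotation intervals %d and %d overlap ([%g, %g] vs [%g, %g])",
                   ov[1], ov[1] + 1L,
                   df$start_s[ov[1]], df$end_s[ov[1]],
                   df$start_s[ov[1] + 1L], df$end_s[ov[1] + 1L]), call. = FALSE)
  }
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Read an annotation track from CSV (`start_s,end_s,label`)
#'
#' @param path CSV file path.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(label = "character"))
  need <- c("start_s", "end_s", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("annotation CSV '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  annotation_track(df$start_s, df$end_s, df$label)
}

#' Write an annotation track to CSV
#' @param ann An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_track"))
  write_csv_full(as.data.frame(ann), path)
  invisible(path)
}

#' Construct an elevation trace
#'
#' Uniformly sampled humeral elevation angle: 0 degrees = arm hanging along
#' gravity, 180 degrees = arm overhead.
#'
#' @param t Sample times in seconds.
#' @param phi_deg Elevation angle per sample, degrees, in \[0, 180\].
#' @param fs_hz Sampling rate; estimated from median time step when missing.
#' @return An object of class `elevation_trace`.
#' @export
elevation_trace <- function(t, phi_deg, fs_hz = NULL) {
  t <- as.numeric(t); phi_deg <- as.numeric(phi_deg)
  if (length(t) != length(phi_deg))
    stop("t and phi_deg must have the same length", call. = FALSE)
  if (!all(is.finite(phi_deg)))
    stop("elevation angles must be finite", call. = FALSE)
  if (any(phi_deg < -1e-9 | phi_deg > 180 + 1e-9))
    stop("elevation angles must lie in [0, 180] degrees", call. = FALSE)
  phi_deg <- pmin(pmax(phi_deg, 0), 180)
  if (length(t) >= 2L && any(diff(t) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (is.null(fs_hz) || !is.finite(fs_hz))
    fs_hz <- if (length(t) >= 2L) 1 / stats::median(diff(t)) else NA_real_
  structure(list(t = t, phi_deg = phi_deg, fs_hz = as.numeric(fs_hz)),
            class = "elevation_trace")
}

#' @export
print.elevation_trace <- function(x, ...) {
  cat(sprintf("<elevation_trace: %d samples, %.6g Hz, range [%.1f, %.1f] deg>\n",
              length(x$t), x$fs_hz,
              if (length(x$phi_deg)) min(x$phi_deg) else NA,
              if (length(x$phi_deg)) max(x$phi_deg) else NA))
  invisible(x)
}

#' Read an elevation trace from CSV (`time_s,elevation_deg`)
#' @param path CSV file path.
#' @return An [elevation_trace()].
#' @export
read_elevation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "elevation_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("elevation CSV '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  elevation_trace(df$time_s, df$elevation_deg)
}

#' Write an elevation trace to CSV
#' @param trace An [elevation_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elevation <- function(trace, path) {
  stopifnot(inherits(trace, "elevation_trace"))
  write_csv_full(data.frame(time_s = trace$t, elevation_deg = trace$phi_deg), path)
  invisible(path)
}
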