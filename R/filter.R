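## Zero-phase Butterworth low-pass filtering.
##
## No signal-processing package is assumed: coefficients come from the
## standard analog Butterworth prototype mapped with the bilinear transform,
## and zero-phase filtering mirrors the usual filtfilt scheme (odd-reflection
## padding + steady-state initial conditions, forward and backward passes).

#' Low-pass Butterworth coefficients
#'
#' @param order Filter order (>= 1).
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param fs_hz Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` polynomial
#'   coefficients (direct form, `a[1] == 1`).
#' @export
butter_lowpass <- function(order, cutoff_hz, fs_hz) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0)
    stop("cutoff_hz must be positive", call. = FALSE)
  if (cutoff_hz >= fs_hz / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fs_hz / 2), call. = FALSE)
  n <- as.integer(order)
  warped <- tan(pi * cutoff_hz / fs_hz)
  k <- seq_len(n)
  ## analog prototype poles on the unit circle, scaled by the warped cutoff
  p_analog <- warped * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  ## bilinear transform; all zeros map to z = -1
  p_z <- (1 + p_analog) / (1 - p_analog)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))
  b <- b * (sum(a) / sum(b))   # unit DC gain
  list(b = b / a[1], a = a / a[1])
}

## Monic polynomial coefficients from roots (descending powers).
poly_from_roots <- function(r) {
  coefs <- c(1 + 0i)
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

## Direct-form II transposed IIR filter with initial state zi * x[1].
iir_filter <- function(b, a, x, zi = NULL) {
  nb <- length(b); na_ <- length(a)
  m <- max(nb, na_) - 1L
  b <- c(b, rep(0, m + 1L - nb))
  a <- c(a, rep(0, m + 1L - na_))
  z <- if (is.null(zi)) rep(0, m) else zi
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 1L)
      for (j in seq_len(m - 1L))
        z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    z[m] <- b[m + 1L] * xi - a[m + 1L] * yi
    y[i] <- yi
  }
  y
}

## Steady-state filter state for a unit step (scipy lfilter_zi equivalent).
filter_zi <- function(b, a) {
  m <- max(length(b), length(a)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[2:(m + 1L)]
  if (m > 1L) comp[cbind(2:m, 1:(m - 1L))] <- 1
  B <- b[2:(m + 1L)] - a[2:(m + 1L)] * b[1]
  solve(diag(m) - t(comp), B)
}

#' Zero-phase filtering (forward-backward)
#'
#' @param b,a Filter coefficients as from [butter_lowpass()].
#' @param x Signal vector.
#' @return Filtered signal of the same length.
#' @export
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  pad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= pad)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)", pad),
         call. = FALSE)
  ## odd reflection about the end points
  ext <- c(2 * x[1] - x[(pad + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + n)]
}

#' Smooth an elevation trace with a zero-phase low-pass filter
#'
#' The result is clamped back to the physical range 0-180 degrees (zero-phase
#' filtering can overshoot at sharp corners).
#'
#' @param trace An [elevation_trace()].
#' @param cutoff_hz Cutoff frequency (default 3 Hz).
#' @param order Butterworth order (default 4).
#' @return A smoothed [elevation_trace()].
#' @export
smooth_trace <- function(trace, cutoff_hz = 3, order = 4) {
  stopifnot(inherits(trace, "elevation_trace"))
  coefs <- butter_lowpass(order, cutoff_hz, trace$fs_hz)
  phi <- filtfilt_zp(coefs$b, coefs$a, trace$phi_deg)
  elevation_trace(trace$t, pmin(pmax(phi, 0), 180), trace$fs_hz)
}
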