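## Independent brute-force oracles. Deliberately naive, loop-based
## re-implementations of the normative procedures; they share nothing with
## the package internals beyond the written contract.

## Alternating extrema by a plain sign-change scan of first differences,
## plateaus collapsed to their first sample.
oracle_turning_points <- function(phi, t) {
  n <- length(phi)
  keep <- rep(TRUE, n)
  if (n >= 2L) for (i in 2:n) if (phi[i] == phi[i - 1L]) keep[i] <- FALSE
  idx <- which(keep)
  v <- phi[idx]
  if (length(idx) < 2L)
    return(data.frame(index = idx[1], t = t[idx[1]], value = v[1],
                      kind = NA_character_))
  d <- diff(v)
  sel <- 1L
  kind <- if (d[1] > 0) "min" else "max"
  if (length(v) >= 3L) {
    for (j in 2:(length(v) - 1L)) {
      if (d[j - 1L] > 0 && d[j] < 0) { sel <- c(sel, j); kind <- c(kind, "max") }
      if (d[j - 1L] < 0 && d[j] > 0) { sel <- c(sel, j); kind <- c(kind, "min") }
    }
  }
  sel <- c(sel, length(v))
  kind <- c(kind, if (d[length(d)] > 0) "max" else "min")
  data.frame(index = idx[sel], t = t[idx[sel]], value = v[sel], kind = kind,
             stringsAsFactors = FALSE)
}

## Brute-force cycle detection: naive pruning (recompute all adjacent ranges
## after every deletion; smallest first, leftmost on ties, endpoints dropped
## singly), then boundary anchoring by linear scans in the raw samples.
oracle_detect_cycles <- function(trace, threshold, band) {
  phi <- trace$phi_deg; tt <- trace$t
  tp <- oracle_turning_points(phi, tt)
  if (nrow(tp) < 3L || anyNA(tp$kind)) return(NULL)
  repeat {
    if (nrow(tp) < 2L) break
    best <- 0L; best_rng <- Inf
    for (i in 1:(nrow(tp) - 1L)) {
      r <- abs(tp$value[i + 1L] - tp$value[i])
      if (r < best_rng) { best_rng <- r; best <- i }
    }
    if (best_rng >= threshold) break
    if (best == 1L) tp <- tp[-1L, , drop = FALSE]
    else if (best == nrow(tp) - 1L) tp <- tp[-nrow(tp), , drop = FALSE]
    else tp <- tp[-c(best, best + 1L), , drop = FALSE]
  }
  if (nrow(tp) < 3L) return(NULL)
  out <- NULL
  for (j in 2:(nrow(tp) - 1L)) {
    if (tp$kind[j] != "max") next
    pk_val <- tp$value[j]
    lo <- tp[j - 1L, ]; hi <- tp[j + 1L, ]
    slim <- min(lo$value + band, pk_val - threshold)
    elim <- min(hi$value + band, pk_val - threshold)
    si <- NA_integer_
    for (i in lo$index:tp$index[j]) if (phi[i] <= slim) si <- i
    ei <- NA_integer_
    for (i in hi$index:tp$index[j]) if (phi[i] <= elim) ei <- i
    seg <- phi[si:ei]
    pk <- si + which.max(seg) - 1L
    out <- rbind(out, data.frame(
      start_s = tt[si], peak_s = tt[pk], end_s = tt[ei],
      rise_deg = max(seg) - phi[si], fall_deg = max(seg) - phi[ei],
      peak_elev_deg = max(seg), median_elev_deg = median(seg)))
  }
  out
}

## Exact two-sided signed-rank p by full 2^n enumeration of sign vectors.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1L)) {
    signs <- as.integer(intToBits(m))[1:n]
    ws[m + 1L] <- sum(r[signs == 1L])
  }
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Smooth-ish random elevation trace: a random walk with occasional larger
## swings, clamped to [0, 180]; generic fodder for oracle-equivalence tests.
random_trace <- function(seed, n = 200, fs = 20) {
  set.seed(seed)
  steps <- rnorm(n - 1, 0, sample(c(0.5, 2, 6), 1))
  phi <- pmin(pmax(30 + cumsum(c(0, steps)), 0), 180)
  elevation_trace((0:(n - 1)) / fs, phi, fs)
}

## Random session spec inside the stated synthetic world: amplitudes at
## least twice the 10 degree threshold, intra-bout gaps well below 7 s,
## rests well above, 50 Hz.
random_session_spec <- function(seed, noise_sd = 0, fs = 50) {
  set.seed(seed * 2L + 1L)
  n_bouts <- sample(1:3, 1)
  bouts <- lapply(seq_len(n_bouts), function(i) {
    nc <- sample(2:5, 1)
    list(n_cycles = nc,
         amplitude_deg = runif(nc, 20, 60),
         cycle_duration_s = runif(1, 1, 3),
         idle_at_top_s = sample(c(0, 0.3), 1),
         intra_bout_gap_s = runif(max(0, nc - 1), 0.5, 5.5))
  })
  rests <- if (n_bouts > 1) runif(n_bouts - 1, 8.5, 20) else numeric()
  session_spec(bouts, rests, fs_hz = fs, angle_noise_sd_deg = noise_sd,
               seed = seed)
}

## Hand construction of a cycle_set at given (start, peak, end) triples.
make_cycles <- function(starts, peaks, ends, span,
                        rise = 30, peak_elev = 30) {
  k <- length(starts)
  cycle_set(data.frame(start_s = starts, peak_s = peaks, end_s = ends,
                       rise_deg = rep_len(rise, k), fall_deg = rep_len(rise, k),
                       peak_elev_deg = rep_len(peak_elev, k),
                       median_elev_deg = rep_len(peak_elev / 2, k)),
            threshold_deg = 10, span_s = span)
}
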