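# Independent brute-force oracles and shared fixtures. The oracles are
# deliberately written as plain per-sample / per-point scans so they share
# no code path with the vectorized implementations they check.

# --- burst detection: exhaustive per-sample scan (magnitude then duration) ---
oracle_bursts <- function(v, rate, thr_vec, min_dur) {
  n <- length(v)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (v[i] >= thr_vec[i]) {
      j <- i
      while (j < n && v[j + 1] >= thr_vec[j + 1]) j <- j + 1L
      if ((j - i + 1) / rate >= min_dur - 1e-12)
        out[[length(out) + 1]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# --- stim pulses: run-length scan with < 2-sample gap merging ---
oracle_pulses <- function(x, rate, threshold) {
  above <- abs(x) >= threshold
  n <- length(above)
  # merge gaps of exactly 1 sample
  for (i in 2:(n - 1)) {
    if (!above[i] && above[i - 1] && above[i + 1]) above[i] <- TRUE
  }
  ends <- c()
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1L
      ends <- c(ends, j / rate)
      i <- j + 1L
    } else i <- i + 1L
  }
  ends
}

# --- MEP extrema: exhaustive enumeration with the same three filters ------
# Interpolates with the same standard spline, then applies prominence,
# same-type separation (larger first) and curvature filters by explicit
# enumeration.
oracle_mep_extrema <- function(samples, rate, min_separation_ms = 0.6,
                               min_prominence = 0.2, d2_threshold = 1.5e6,
                               interp = "cubic") {
  n <- length(samples)
  dt <- 1 / rate
  t_orig <- (seq_len(n) - 1) * dt
  tt <- seq(0, t_orig[n], by = dt / 2)
  y <- if (interp == "cubic") stats::spline(t_orig, samples, xout = tt,
                                            method = "fmm")$y
       else stats::approx(t_orig, samples, xout = tt)$y
  m <- length(y)
  h <- dt / 2
  prominence_at <- function(z, i) {
    lm <- z[i]; j <- i
    while (j > 1 && z[j - 1] <= z[i]) { j <- j - 1; lm <- min(lm, z[j]) }
    if (j > 1) lm <- min(lm, z[j - 1])
    rm <- z[i]; j <- i
    while (j < m && z[j + 1] <= z[i]) { j <- j + 1; rm <- min(rm, z[j]) }
    if (j < m) rm <- min(rm, z[j + 1])
    z[i] - max(lm, rm)
  }
  one_type <- function(z) {
    cand <- c()
    for (i in 2:(m - 1)) {
      if (z[i] > z[i - 1] && z[i] >= z[i + 1]) cand <- c(cand, i)
    }
    cand <- cand[vapply(cand, function(i) prominence_at(z, i),
                        numeric(1)) >= min_prominence - 1e-12]
    if (!length(cand)) return(integer(0))
    ord <- cand[order(-z[cand], cand)]
    kept <- c()
    for (i in ord) {
      ok <- TRUE
      for (k in kept) {
        if (abs(tt[i] - tt[k]) < min_separation_ms * 1e-3 - 1e-12) ok <- FALSE
      }
      if (ok) kept <- c(kept, i)
    }
    kept <- sort(kept)
    res <- c()
    for (i in kept) {
      d2 <- (y[i - 1] - 2 * y[i] + y[i + 1]) / h^2
      if (abs(d2) >= d2_threshold) res <- c(res, i)
    }
    res
  }
  pk <- one_type(y)
  tr <- one_type(-y)
  list(peak_times_ms = tt[pk] * 1e3, trough_times_ms = tt[tr] * 1e3)
}

# --- event matching: exhaustive optimal assignment on tiny inputs ---------
# Maximizes the number of detected/annotated pairs compatible under the
# overlap-or-onset-tolerance rule by trying all injective assignments.
oracle_match_count <- function(detected, steps, tolerance_s) {
  nd <- nrow(detected); na <- nrow(steps)
  if (nd == 0 || na == 0) return(0L)
  compatible <- matrix(FALSE, nd, na)
  for (i in seq_len(nd)) for (j in seq_len(na)) {
    compatible[i, j] <-
      (steps$onset_s[j] < detected$stance_end_s[i] &&
         steps$offset_s[j] > detected$swing_start_s[i]) ||
      abs(detected$zero_cross_s[i] - steps$onset_s[j]) <= tolerance_s
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (i > nd) { best <<- max(best, count); return(invisible(NULL)) }
    recurse(i + 1, used, count)
    for (j in seq_len(na)) {
      if (!used[j] && compatible[i, j]) {
        used[j] <- TRUE
        recurse(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, na), 0L)
  best
}

# --- shared step-criteria scenario ----------------------------------------
# Hand-constructed relative-difference waveform with one flexion peak
# followed by an extension phase, plus burst tables. Arguments toggle the
# individual detection gates.
make_step_scenario <- function(rate = 1000,
                               peak_value = 0.5,
                               peak_t = 1.0,
                               zc_t = 1.2,
                               ta_burst = c(0.7, 1.15),
                               sol_burst = c(1.15, 2.25),
                               neg_depth = 0.3,
                               neg_end_t = 2.2,
                               extra_peak_t = NULL,
                               extra_peak_value = 0.3) {
  dur <- 3
  n <- dur * rate
  t <- (seq_len(n) - 1) / rate
  v <- numeric(n)
  # rise from swing start (0.5 s) to the peak, fall to the crossing,
  # negative lobe, then back to zero
  rise <- t >= 0.5 & t <= peak_t
  v[rise] <- peak_value * (t[rise] - 0.5) / (peak_t - 0.5)
  fall <- t > peak_t & t < zc_t
  v[fall] <- peak_value * (zc_t - t[fall]) / (zc_t - peak_t)
  negp <- t >= zc_t & t <= neg_end_t
  v[negp] <- -neg_depth * sin(pi * (t[negp] - zc_t) / (neg_end_t - zc_t))
  if (!is.null(extra_peak_t)) {
    bump <- abs(t - extra_peak_t) < 0.02
    v[bump] <- v[bump] +
      extra_peak_value * cos(pi * (t[bump] - extra_peak_t) / 0.04)^2
  }
  bdf <- function(b, muscle) data.frame(
    side = "L", muscle = muscle, start_s = b[1], end_s = b[2],
    duration_s = b[2] - b[1], stringsAsFactors = FALSE)
  list(
    diff = relative_difference(v, numeric(n), rate, side = "L"),
    ta_bursts = bdf(ta_burst, "TA"),
    sol_bursts = bdf(sol_burst, "Sol")
  )
}

# random smooth MEP-like epoch: a few random Gaussian lobes
random_smooth_epoch <- function(rate = 10000, epoch_s = 0.025) {
  n <- round(epoch_s * rate)
  t_ms <- (seq_len(n) - 1) / rate * 1000
  y <- numeric(n)
  for (k in seq_len(sample(2:5, 1))) {
    y <- y + stats::runif(1, -1, 1) *
      exp(-(t_ms - stats::runif(1, 1.5, 23))^2 / (2 * stats::runif(1, 0.3, 0.9)^2))
  }
  y
}
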