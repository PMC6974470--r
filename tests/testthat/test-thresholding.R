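test_that("rest discovery spans a flat bin and excludes an embedded burst", {
  rate <- 1000
  env <- envelope(rep(0.01, 10 * rate), rate)
  r <- find_rest_period(env, c(0, 10))
  expect_equal(r$start_s, 0)
  expect_equal(r$end_s, 10)
  expect_equal(r$mu_rest, 0.01)
  expect_equal(r$sigma_rest, 0)

  v <- rep(0.01, 10 * rate)
  v[seq(4 * rate, 5 * rate)] <- 1.0  # 1 s burst mid-bin
  r2 <- find_rest_period(envelope(v, rate), c(0, 10))
  expect_lt(abs(r2$mu_rest - 0.01), 1e-9)
  # grown window stays clear of the burst samples
  expect_true(r2$end_s <= 4.0 + 0.011 || r2$start_s >= 5.0)
  expect_error(find_rest_period(envelope(rep(1, 15), rate), c(0, 0.015)),
               "2 averaging blocks")
})

test_that("rest growth seeds in the lower plateau and stops at a step change", {
  rate <- 1000
  v <- c(rep(0.01, 5 * rate), rep(0.02, 5 * rate))
  # absolute mode, the printed constant: step of 0.01 per 10 ms = 1.0/s > 0.1
  r <- find_rest_period(envelope(v, rate), c(0, 10), dmax_mode = "absolute",
                        dmax = 0.1, use_log = FALSE)
  expect_equal(r$mu_rest, 0.01)
  expect_equal(r$start_s, 0)
  expect_equal(r$end_s, 5)
  # relative mode: the jump is 100x the seed level per second -> same stop
  r2 <- find_rest_period(envelope(v, rate), c(0, 10), dmax_mode = "relative",
                         dmax_rel = 50, use_log = FALSE)
  expect_equal(r2$end_s, 5)
})

test_that("log-deviation criterion stops slow ramps the differential misses", {
  rate <- 1000
  # gentle exponential ramp: per-block differential tiny, cumulative drift big
  t <- seq(0, 10, length.out = 10 * rate)
  v <- 0.01 * exp(0.4 * t)
  ramp_only <- find_rest_period(envelope(v, rate), c(0, 10),
                                dmax_mode = "relative", dmax_rel = 1e6,
                                log_thresh = 300, use_log = TRUE)
  no_log <- find_rest_period(envelope(v, rate), c(0, 10),
                             dmax_mode = "relative", dmax_rel = 1e6,
                             use_log = FALSE)
  expect_lt(ramp_only$end_s - ramp_only$start_s,
            no_log$end_s - no_log$start_s)
  expect_equal(no_log$end_s - no_log$start_s, 10)
})

test_that("threshold formula is mu + J*sigma with per-muscle time criteria", {
  r <- structure(list(mu_rest = 0.10, sigma_rest = 0.02),
                 class = "rest_segment")
  expect_equal(compute_threshold(r, J = 7, muscle = "TA")$magnitude, 0.24)
  expect_equal(compute_threshold(r, J = 7, muscle = "TA")$min_duration_s, 0.1)
  expect_equal(compute_threshold(r, J = 7, muscle = "Sol")$min_duration_s, 0.3)
  r0 <- structure(list(mu_rest = 0.5, sigma_rest = 0), class = "rest_segment")
  expect_equal(compute_threshold(r0, J = 7)$magnitude, 0.5)
  r1 <- structure(list(mu_rest = 0, sigma_rest = 1), class = "rest_segment")
  expect_equal(compute_threshold(r1, J = 7)$magnitude, 7)
  expect_error(compute_threshold(r, J = 0), "J must be > 0")
})

test_that("double thresholding applies magnitude then duration criteria", {
  rate <- 1000
  thr_ta <- data.frame(start_s = 0, end_s = 10, magnitude = 0.1,
                       min_duration_s = 0.1)
  thr_sol <- data.frame(start_s = 0, end_s = 10, magnitude = 0.1,
                        min_duration_s = 0.3)
  flat <- envelope(rep(0.05, 10 * rate), rate, muscle = "TA")
  expect_equal(nrow(detect_bursts(flat, thr_ta)), 0)

  v <- rep(0.01, 10 * rate)
  v[(2 * rate + 1):(2.5 * rate)] <- 0.5  # 0.5 s plateau
  ta <- detect_bursts(envelope(v, rate, muscle = "TA"), thr_ta)
  expect_equal(nrow(ta), 1)
  expect_equal(ta$duration_s, 0.5)
  expect_equal(ta$start_s, 2.0)
  expect_equal(ta$end_s, 2.5)

  w <- rep(0.01, 10 * rate)
  w[(2 * rate + 1):(2.2 * rate)] <- 0.5  # 0.2 s < 0.3 s extensor criterion
  sol <- detect_bursts(envelope(w, rate, muscle = "Sol"), thr_sol)
  expect_equal(nrow(sol), 0)  # magnitude met, time criterion not
})

test_that("burst detection equals the exhaustive per-sample oracle", {
  set.seed(5)
  rate <- 1000
  for (rep in 1:8) {
    v <- abs(stats::filter(rnorm(5000), rep(1 / 30, 30), sides = 2))
    v[is.na(v)] <- 0
    v <- as.numeric(v)
    thr <- data.frame(start_s = c(0, 2.5), end_s = c(2.5, 5),
                      magnitude = runif(2, 0.02, 0.08),
                      min_duration_s = 0.05)
    env <- envelope(v, rate, muscle = "TA")
    got <- detect_bursts(env, thr)
    thr_vec <- c(rep(thr$magnitude[1], 2500), rep(thr$magnitude[2], 2500))
    want <- oracle_bursts(v, rate, thr_vec, 0.05)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, (want[, 1] - 1) / rate)
      expect_equal(got$end_s, want[, 2] / rate)
    }
  }
})

test_that("burst sample set shrinks monotonically as J grows", {
  set.seed(9)
  rate <- 1000
  v <- abs(rnorm(10 * rate, sd = 0.02))
  v[(3 * rate):(4 * rate)] <- v[(3 * rate):(4 * rate)] + 0.3
  env <- envelope(v, rate, muscle = "TA")
  rest <- find_rest_period(env, c(0, 10))
  prev <- NULL
  for (J in c(3, 5, 7, 9)) {
    thr <- compute_threshold(rest, J = J, muscle = "TA")
    b <- detect_bursts(env, data.frame(start_s = 0, end_s = 10,
                                       magnitude = thr$magnitude,
                                       min_duration_s = 0.1))
    in_burst <- rep(FALSE, length(v))
    for (k in seq_len(nrow(b))) {
      in_burst[seq(b$start_s[k] * rate + 1, b$end_s[k] * rate)] <- TRUE
    }
    if (!is.null(prev)) expect_true(all(prev | !in_burst))  # subset of prev
    prev <- in_burst
  }
})

test_that("thresholds scale with the envelope and burst intervals are unchanged", {
  set.seed(13)
  rate <- 1000
  v <- abs(rnorm(10 * rate, sd = 0.01))
  v[(6 * rate):(6.8 * rate)] <- v[(6 * rate):(6.8 * rate)] + 0.2
  k <- 3.7
  for (mode in c("relative", "absolute")) {
    dmax1 <- 0.1
    dmax2 <- if (mode == "absolute") k * dmax1 else dmax1
    r1 <- find_rest_period(envelope(v, rate), c(0, 10), dmax = dmax1,
                           dmax_mode = mode)
    r2 <- find_rest_period(envelope(k * v, rate), c(0, 10), dmax = dmax2,
                           dmax_mode = mode)
    expect_equal(r2$mu_rest, k * r1$mu_rest, tolerance = 1e-12)
    expect_equal(r2$sigma_rest, k * r1$sigma_rest, tolerance = 1e-12)
    t1 <- compute_threshold(r1, muscle = "TA")
    t2 <- compute_threshold(r2, muscle = "TA")
    expect_equal(t2$magnitude, k * t1$magnitude, tolerance = 1e-12)
    b1 <- detect_bursts(envelope(v, rate, muscle = "TA"),
                        data.frame(start_s = 0, end_s = 10,
                                   magnitude = t1$magnitude,
                                   min_duration_s = 0.1))
    b2 <- detect_bursts(envelope(k * v, rate, muscle = "TA"),
                        data.frame(start_s = 0, end_s = 10,
                                   magnitude = t2$magnitude,
                                   min_duration_s = 0.1))
    expect_equal(b1$start_s, b2$start_s)
    expect_equal(b1$end_s, b2$end_s)
  }
})

test_that("per-bin thresholds cover the span and short tails inherit", {
  set.seed(17)
  rate <- 1000
  env <- envelope(abs(rnorm(21 * rate, sd = 0.01)), rate, muscle = "Sol")
  thr <- compute_bin_thresholds(env)
  expect_equal(nrow(thr), 3)
  expect_equal(thr$end_s[3], 21)
  # 1 s tail (< 2 s minimum) inherits the previous bin's statistics
  env2 <- envelope(abs(rnorm(11 * rate, sd = 0.01)), rate, muscle = "Sol")
  thr2 <- compute_bin_thresholds(env2)
  expect_equal(nrow(thr2), 2)
  expect_equal(thr2$magnitude[2], thr2$magnitude[1])
  expect_true(all(thr2$min_duration_s == 0.3))
  # burst intervals from detect_bursts always satisfy their own invariants
  b <- detect_bursts(env, thr)
  if (nrow(b)) {
    expect_true(all(b$end_s > b$start_s))
    expect_true(all(b$duration_s >= 0.3))
  }
})
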