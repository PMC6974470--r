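test_that("pair normalization maps to [0,1], guards zeros, cancels joint scale", {
  rate <- 1000
  ta <- envelope(c(rep(0.5, 10), 2.0, rep(0.5, 10)), rate)
  sol <- envelope(rep(1, 21), rate)
  nrm <- normalize_pair(ta, sol)
  expect_equal(max(nrm$ta), 1.0)
  expect_equal(nrm$sol, rep(1, 21))
  z <- normalize_pair(envelope(rep(0, 21), rate), sol)
  expect_equal(z$ta, rep(0, 21))
  ta2 <- ta; ta2$values <- ta$values * 4.2
  sol2 <- sol; sol2$values <- sol$values * 4.2
  expect_equal(normalize_pair(ta2, sol2), nrm)
})

test_that("relative difference is signed flexor-minus-extensor coordination", {
  d <- relative_difference(c(1, 0.5, 0), c(0, 0.5, 1), rate = 100, side = "L")
  expect_equal(d$values, c(1, 0, -1))
  expect_true(all(abs(d$values) <= 1))
  expect_error(relative_difference(1:3 / 3, 1:2 / 2, 100), "equal length")
})

test_that("a canonical flexion peak followed by extension registers one step", {
  sc <- make_step_scenario()
  st <- detect_steps(sc$diff, sc$ta_bursts, sc$sol_bursts)
  expect_equal(nrow(st), 1)
  expect_equal(st$peak_time_s, 1.0, tolerance = 2e-3)
  expect_equal(st$zero_cross_s, 1.2, tolerance = 2e-3)
  expect_true(st$swing_start_s <= st$peak_time_s)
  expect_true(st$peak_time_s < st$zero_cross_s)
  expect_true(st$zero_cross_s <= st$stance_end_s)
})

test_that("each detection gate independently vetoes the step", {
  # magnitude gate: peak below the 0.01 difference threshold
  low <- make_step_scenario(peak_value = 0.005, neg_depth = 0.003)
  expect_equal(nrow(detect_steps(low$diff, low$ta_bursts, low$sol_bursts)), 0)
  # flexor-burst gate: peak not inside an active TA burst
  off <- make_step_scenario(ta_burst = c(0.2, 0.5))
  expect_equal(nrow(detect_steps(off$diff, off$ta_bursts, off$sol_bursts)), 0)
  # follow-window gate: signal turns negative only 0.7 s after the peak
  late <- make_step_scenario(zc_t = 1.7, sol_burst = c(1.6, 2.8),
                             neg_end_t = 2.75)
  expect_equal(nrow(detect_steps(late$diff, late$ta_bursts, late$sol_bursts)), 0)
  # extensor-duration gate: Sol burst of 0.2 s < 0.25 s
  short <- make_step_scenario(sol_burst = c(1.15, 1.35))
  expect_equal(nrow(detect_steps(short$diff, short$ta_bursts,
                                 short$sol_bursts)), 0)
  # empty burst lists are a valid no-detection input
  none <- make_step_scenario()
  expect_equal(nrow(detect_steps(none$diff, none$ta_bursts[0, ],
                                 none$sol_bursts)), 0)
})

test_that("the last qualifying maximum in a flexor burst wins, with 0.2 s spacing", {
  # second maximum only 0.15 s before the main peak: suppressed by the
  # separation rule, so the earlier (first accepted) candidate registers
  near <- make_step_scenario(extra_peak_t = 0.85, extra_peak_value = 0.2)
  st_near <- detect_steps(near$diff, near$ta_bursts, near$sol_bursts)
  expect_equal(nrow(st_near), 1)
  expect_equal(st_near$peak_time_s, 0.85, tolerance = 2e-3)
  # 0.25 s before the main peak: both candidates accepted, the later
  # (last in the burst) is selected
  far <- make_step_scenario(extra_peak_t = 0.75, extra_peak_value = 0.2)
  st_far <- detect_steps(far$diff, far$ta_bursts, far$sol_bursts)
  expect_equal(nrow(st_far), 1)
  expect_equal(st_far$peak_time_s, 1.0, tolerance = 2e-3)
})

test_that("cycle windows land on zero crossings and clip at extensor burst end", {
  rate <- 1000
  t <- (0:(4 * rate - 1)) / rate
  v <- sin(2 * pi * (t - 1))  # zeros at 1, 1.5, 2, ...; peak at 1.25
  d <- relative_difference(v, numeric(length(v)), rate, side = "L")
  sol <- data.frame(side = "L", muscle = "Sol", start_s = 1.5, end_s = 3.0,
                    duration_s = 1.5)
  ev <- step_cycle_window(d, peak_idx = round(1.25 * rate) + 1,
                          zc_idx = round(1.5 * rate) + 2,
                          sol_end_s = 3.0)
  expect_equal(ev$swing_start_s, 1.0, tolerance = 2e-3)
  expect_equal(ev$stance_end_s, 2.0, tolerance = 2e-3)
  # extensor burst ending first truncates the stance phase
  ev2 <- step_cycle_window(d, peak_idx = round(1.25 * rate) + 1,
                           zc_idx = round(1.5 * rate) + 2, sol_end_s = 1.8)
  expect_equal(ev2$stance_end_s, 1.8)
  # positive from the start: swing clamps to segment start with a warning
  d2 <- relative_difference(rep(0.5, 1000), numeric(1000), rate, side = "L")
  expect_warning(
    ev3 <- step_cycle_window(d2, peak_idx = 500, zc_idx = 600, sol_end_s = 0.9),
    "clamping")
  expect_equal(ev3$swing_start_s, 0)
})

test_that("raising the difference threshold never adds events", {
  sc <- make_step_scenario()
  n_prev <- Inf
  for (thr in c(0.005, 0.01, 0.3, 0.6)) {
    p <- step_detection_params(diff_threshold = thr)
    n <- nrow(detect_steps(sc$diff, sc$ta_bursts, sc$sol_bursts, p))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  expect_error(step_detection_params(diff_threshold = 0), "must be > 0")
})

test_that("activity metrics summarise rate, stance, IEMG and percent change", {
  ev <- data.frame(side = "L",
                   swing_start_s = seq(0, by = 30, length.out = 12),
                   peak_time_s = seq(10, by = 30, length.out = 12),
                   zero_cross_s = seq(10.2, by = 30, length.out = 12),
                   stance_end_s = seq(12.2, by = 30, length.out = 12))
  m <- activity_metrics(ev, duration_s = 360, reference_count = 4)
  expect_equal(m$mean_steps_per_min, 2.0)  # 12 events in 6 min
  expect_equal(m$pct_change, 300)          # 12 vs reference 4
  expect_equal(m$mean_stance_s, 2.0, tolerance = 1e-9)
  expect_true(is.na(activity_metrics(ev, duration_s = 360,
                                     reference_count = 0)$pct_change))
  env <- envelope(rep(0.4, 1000), 100)
  ci <- cumulative_iemg(env, n_out = 50)
  expect_equal(ci$value[1], 0)
  expect_equal(ci$value[nrow(ci)], 1)
  lin <- seq(0, 1, length.out = nrow(ci))
  expect_lt(max(abs(ci$value - lin)), 0.01)  # constant envelope -> straight line
})

test_that("detected events keep their ordering invariant and one-per-burst rule", {
  sim <- suppressWarnings(
    simulate_recording(sim_config(duration_s = 60, n_step_bouts = 3,
                                  steps_per_bout = 4, seed = 7)))
  res <- suppressWarnings(run_step_detection(sim$recording))
  st <- res$steps
  expect_gt(nrow(st), 0)
  expect_true(all(st$swing_start_s <= st$peak_time_s))
  expect_true(all(st$peak_time_s < st$zero_cross_s))
  expect_true(all(st$zero_cross_s <= st$stance_end_s))
  # at most one event per flexor burst
  tb <- res$bursts[res$bursts$muscle == "TA", ]
  for (s in c("L", "R")) {
    stx <- st[st$side == s, ]
    tbx <- tb[tb$side == s, ]
    if (nrow(stx) && nrow(tbx)) {
      owner <- findInterval(stx$peak_time_s, sort(tbx$start_s))
      expect_false(any(duplicated(owner)))
    }
  }
})
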