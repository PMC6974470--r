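#' Step-detection parameters
#'
#' Numeric criteria used by [detect_steps()]: a registered step needs a
#' positive relative-difference peak greater than `diff_threshold`, lying
#' inside an active flexor (TA) burst, followed by a negative
#' relative-difference phase within `follow_window_s`, with that negative
#' phase overlapping an extensor (Sol) burst of at least `sol_burst_min_s`;
#' candidate local maxima must be `peak_separation_s` apart and only the
#' last qualifying maximum inside each TA burst is kept.
#'
#' @param follow_window_s time allowed between the peak and the negative
#'   phase (default 0.5 s).
#' @param diff_threshold minimum peak magnitude on the normalized difference
#'   signal (default 0.01).
#' @param sol_burst_min_s minimum extensor-burst duration (default 0.25 s).
#' @param peak_separation_s minimum spacing between candidate maxima
#'   (default 0.2 s).
#' @return list of class `step_detection_params`.
#' @export
step_detection_params <- function(follow_window_s = 0.5,
                                  diff_threshold = 0.01,
                                  sol_burst_min_s = 0.25,
                                  peak_separation_s = 0.2) {
  p <- list(follow_window_s = follow_window_s,
            diff_threshold = diff_threshold,
            sol_burst_min_s = sol_burst_min_s,
            peak_separation_s = peak_separation_s)
  if (any(unlist(p) <= 0)) stop("all step-detection parameters must be > 0")
  structure(p, class = "step_detection_params")
}

#' Normalize a flexor/extensor envelope pair
#'
#' Each channel is divided by its own maximum over the current processing
#' segment, mapping it into `[0, 1]`; an all-zero channel maps to all zeros
#' rather than dividing by zero. Joint rescaling of both raw channels leaves
#' the normalized pair unchanged, which substitutes for the missing
#' force-EMG calibration.
#'
#' @param ta_env,sol_env [envelope()] objects of equal length and rate.
#' @return list with numeric vectors `ta` and `sol` in `[0, 1]`.
#' @export
normalize_pair <- function(ta_env, sol_env) {
  if (length(ta_env$values) != length(sol_env$values))
    stop("envelopes must have equal length")
  if (ta_env$rate != sol_env$rate) stop("envelopes must share a rate")
  norm1 <- function(v) {
    m <- max(v)
    if (m <= 0) rep(0, length(v)) else v / m
  }
  list(ta = norm1(ta_env$values), sol = norm1(sol_env$values))
}

#' Flexor-extensor relative-difference signal
#'
#' Pointwise normalized TA minus normalized Sol, bounded in `[-1, 1]`.
#' Positive values indicate net ankle flexion (swing), negative values net
#' extension (stance).
#'
#' @param ta_norm,sol_norm normalized vectors from [normalize_pair()].
#' @param rate sampling rate in Hz.
#' @param side `"L"` or `"R"`.
#' @param t0 start offset in seconds.
#' @return object of class `relative_difference` with fields `values`,
#'   `rate`, `side`, `t0`.
#' @export
relative_difference <- function(ta_norm, sol_norm, rate,
                                side = NA_character_, t0 = 0) {
  if (length(ta_norm) != length(sol_norm))
    stop("inputs must have equal length")
  structure(list(values = ta_norm - sol_norm, rate = rate, side = side,
                 t0 = t0),
            class = "relative_difference")
}

# indices of local maxima: strictly above left neighbour, at or above right
# (the first sample of a plateau represents it)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Detect step-like events from the relative-difference signal
#'
#' Candidate peaks are local maxima of the relative difference that are
#' (a) positive and above `diff_threshold`, (b) inside an active TA burst,
#' and (c) at least `peak_separation_s` after the previously accepted
#' candidate; within each TA burst only the last surviving candidate is
#' kept. A kept candidate is registered as a step when the signal turns
#' strictly negative within `follow_window_s` after the peak with the
#' negative phase overlapping (by at least one sample) a Sol burst lasting
#' at least `sol_burst_min_s`; successive negative runs inside the follow
#' window are examined in order and the first one during an active
#' extensor burst registers the event, its first sample giving the
#' flexion-to-extension crossing time. The registered event carries the
#' swing/stance cycle window filled by [step_cycle_window()].
#'
#' @param diff a [relative_difference()].
#' @param ta_bursts,sol_bursts burst data.frames from [detect_bursts()] for
#'   the same side.
#' @param params a [step_detection_params()].
#' @return data.frame of step events: `side`, `swing_start_s`,
#'   `peak_time_s`, `zero_cross_s`, `stance_end_s` (one row per event,
#'   at most one per TA burst).
#' @export
detect_steps <- function(diff, ta_bursts, sol_bursts,
                         params = step_detection_params()) {
  stopifnot(inherits(diff, "relative_difference"))
  empty <- data.frame(side = character(0), swing_start_s = numeric(0),
                      peak_time_s = numeric(0), zero_cross_s = numeric(0),
                      stance_end_s = numeric(0), stringsAsFactors = FALSE)
  if (is.null(ta_bursts) || nrow(ta_bursts) == 0 ||
      is.null(sol_bursts) || nrow(sol_bursts) == 0) return(empty)
  v <- diff$values
  rate <- diff$rate
  t_of <- function(i) diff$t0 + (i - 1) / rate
  pk <- local_maxima(v)
  pk <- pk[v[pk] > params$diff_threshold]
  if (!length(pk)) return(empty)
  tpk <- t_of(pk)
  # inside an active TA burst (half-open interval)
  burst_of <- findInterval(tpk, ta_bursts$start_s)
  inside <- burst_of >= 1 & tpk < ta_bursts$end_s[pmax(burst_of, 1)]
  pk <- pk[inside]; tpk <- tpk[inside]; burst_of <- burst_of[inside]
  if (!length(pk)) return(empty)
  # candidate-level separation chain, then last survivor per TA burst
  keep <- logical(length(pk))
  last_t <- -Inf
  for (i in seq_along(pk)) {
    if (tpk[i] - last_t >= params$peak_separation_s - 1e-12) {
      keep[i] <- TRUE
      last_t <- tpk[i]
    }
  }
  pk <- pk[keep]; tpk <- tpk[keep]; burst_of <- burst_of[keep]
  sel <- !duplicated(burst_of, fromLast = TRUE)
  pk <- pk[sel]; tpk <- tpk[sel]
  sol_ok <- sol_bursts[sol_bursts$duration_s >= params$sol_burst_min_s - 1e-12, ,
                       drop = FALSE]
  n <- length(v)
  follow <- round(params$follow_window_s * rate)
  rows <- list()
  for (i in seq_along(pk)) {
    j0 <- pk[i] + 1L
    j1 <- min(n, pk[i] + follow)
    if (j0 > j1) next
    neg <- which(v[j0:j1] < 0)
    if (!length(neg)) next
    # successive strictly-negative runs inside the follow window; the step
    # registers on the first one overlapping a qualifying extensor burst
    runs <- split(neg, cumsum(c(1, diff(neg) != 1)))
    zc <- NA_integer_; ov <- integer(0)
    for (r in runs) {
      r0 <- j0 + r[1] - 1L
      # extend the run past the follow window to its true end
      run_end <- j0 + r[length(r)] - 1L
      while (run_end < n && v[run_end + 1] < 0) run_end <- run_end + 1L
      neg_start <- t_of(r0)
      neg_end <- t_of(run_end) + 1 / rate
      ov <- which(sol_ok$start_s < neg_end & sol_ok$end_s > neg_start)
      if (length(ov)) { zc <- r0; break }
    }
    if (is.na(zc)) next
    ev <- step_cycle_window(diff, peak_idx = pk[i], zc_idx = zc,
                            sol_end_s = sol_ok$end_s[ov[1]])
    rows[[length(rows) + 1]] <- data.frame(
      side = diff$side, swing_start_s = ev$swing_start_s,
      peak_time_s = tpk[i], zero_cross_s = t_of(zc),
      stance_end_s = ev$stance_end_s, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Delimit the full step cycle around a detected event
#'
#' The cycle spans the beginning of swing to the end of stance:
#' `swing_start` is the last time at or before the peak where the
#' relative difference is non-positive (clamped, with a warning, to the
#' segment start when the signal is positive from the outset);
#' `stance_end` is the earlier of the first return of the signal to `>= 0`
#' after the flexion-to-extension crossing and the end of the overlapping
#' Sol burst.
#'
#' @param diff a [relative_difference()].
#' @param event one-row data.frame from [detect_steps()] (used when
#'   `peak_idx`/`zc_idx` are not given directly).
#' @param sol_bursts burst data.frame used to locate the overlapping
#'   extensor burst (when `sol_end_s` is not given).
#' @param peak_idx,zc_idx sample indices of the peak and zero crossing
#'   (internal fast path).
#' @param sol_end_s end of the qualifying Sol burst in seconds.
#' @return list with `swing_start_s` and `stance_end_s`.
#' @export
step_cycle_window <- function(diff, event = NULL, sol_bursts = NULL,
                              peak_idx = NULL, zc_idx = NULL,
                              sol_end_s = NULL) {
  v <- diff$values
  rate <- diff$rate
  t_of <- function(i) diff$t0 + (i - 1) / rate
  if (is.null(peak_idx)) {
    peak_idx <- round((event$peak_time_s - diff$t0) * rate) + 1L
    zc_idx <- round((event$zero_cross_s - diff$t0) * rate) + 1L
  }
  if (is.null(sol_end_s)) {
    if (is.null(sol_bursts) || nrow(sol_bursts) == 0)
      stop("need sol_bursts or sol_end_s to delimit the stance phase")
    tz <- t_of(zc_idx)
    ov <- which(sol_bursts$start_s <= tz & sol_bursts$end_s > tz)
    if (!length(ov)) ov <- which(sol_bursts$end_s > tz)[1]
    if (is.na(ov[1])) stop("no extensor burst overlaps the stance phase")
    sol_end_s <- sol_bursts$end_s[ov[1]]
  }
  nonpos <- which(v[seq_len(peak_idx)] <= 0)
  if (length(nonpos)) {
    swing_start <- t_of(nonpos[length(nonpos)])
  } else {
    warning("relative difference positive from segment start; ",
            "clamping swing start to segment start")
    swing_start <- diff$t0
  }
  n <- length(v)
  ret <- if (zc_idx < n) which(v[(zc_idx + 1):n] >= 0) else integer(0)
  ret_t <- if (length(ret)) t_of(zc_idx + ret[1]) else Inf
  stance_end <- min(ret_t, sol_end_s)
  list(swing_start_s = swing_start, stance_end_s = stance_end)
}

#' Aggregate activity metrics over detected step events
#'
#' Summaries of a detection run: steps per minute (per 1-minute bin and
#' mean), per-event stance periods (`stance_end - zero_cross`), cumulative
#' integrated EMG per envelope normalized to `[0, 1]` over the recording,
#' and the percent change in step count relative to a reference (baseline)
#' count, with 100% meaning no change.
#'
#' @param events step-event data.frame from [detect_steps()].
#' @param envelopes optional named list of [envelope()] objects for the
#'   cumulative IEMG curves.
#' @param duration_s recording duration in seconds.
#' @param reference_count optional baseline step count; percent change is
#'   `NA` when the reference is zero or missing.
#' @param n_curve number of points on each cumulative IEMG curve.
#' @return list with `steps_per_min` (data.frame `minute`, `n`),
#'   `mean_steps_per_min`, `stance_s`, `mean_stance_s`, `n_events`,
#'   `pct_change`, and `cum_iemg` (named list of data.frames `t_s`, `value`).
#' @export
activity_metrics <- function(events, envelopes = NULL, duration_s,
                             reference_count = NULL, n_curve = 200) {
  n_min <- max(1, ceiling(duration_s / 60 - 1e-9))
  minute <- seq_len(n_min) - 1L
  counts <- if (nrow(events)) {
    tabulate(pmin(floor(events$peak_time_s / 60) + 1L, n_min), nbins = n_min)
  } else rep(0L, n_min)
  stance <- if (nrow(events)) events$stance_end_s - events$zero_cross_s else numeric(0)
  pct <- if (is.null(reference_count) || !is.finite(reference_count) ||
             reference_count == 0) NA_real_ else 100 * nrow(events) / reference_count
  cum <- NULL
  if (!is.null(envelopes)) {
    cum <- lapply(envelopes, function(e) cumulative_iemg(e, n_curve))
  }
  list(
    steps_per_min = data.frame(minute = minute, n = counts),
    mean_steps_per_min = nrow(events) / (duration_s / 60),
    stance_s = stance,
    mean_stance_s = if (length(stance)) mean(stance) else NA_real_,
    n_events = nrow(events),
    pct_change = pct,
    cum_iemg = cum
  )
}

#' Normalized cumulative integrated EMG of an envelope
#'
#' Cumulative trapezoidal integral of the (non-negative) envelope,
#' normalized to end at 1; a constant envelope yields a straight 0-to-1
#' line.
#'
#' @param env an [envelope()].
#' @param n_out number of output points.
#' @return data.frame with `t_s` and `value` in `[0, 1]`.
#' @export
cumulative_iemg <- function(env, n_out = 200) {
  v <- env$values
  n <- length(v)
  ct <- c(0, cumsum((v[-1] + v[-n]) / 2)) / env$rate
  total <- ct[n]
  if (total > 0) ct <- ct / total
  idx <- unique(round(seq(1, n, length.out = min(n_out, n))))
  data.frame(t_s = env$t0 + (idx - 1) / env$rate, value = ct[idx])
}
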