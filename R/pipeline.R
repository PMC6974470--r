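#' Run the full step-detection pipeline on a recording
#'
#' End-to-end orchestration: the recording is split into processing
#' segments (10 min by default); within each segment every channel is
#' conditioned ([condition()]), per-bin burst thresholds are computed
#' ([compute_bin_thresholds()]) and bursts marked ([detect_bursts()]); per
#' side, the envelopes are normalized over the segment
#' ([normalize_pair()]), the relative-difference signal formed and step
#' events registered ([detect_steps()]). Results are reported in recording
#' time across segments. Flexor bursts with no registered step are
#' reported separately as non-step activity.
#'
#' @param rec an [emg_recording()] with the four step-detection channels.
#' @param config configuration list, see [tokeda_config()].
#' @param sides sides to process (default both).
#' @param keep_envelopes keep per-segment envelopes in the result (memory
#'   heavy on long recordings).
#' @return object of class `tokeda_result`: list with `steps` (event
#'   data.frame), `bursts`, `thresholds`, `non_step_ta_bursts` (count of
#'   flexor bursts without a registered step), `duration_s`, `config`, and
#'   optionally `envelopes`.
#' @export
run_step_detection <- function(rec, config = tokeda_config(),
                               sides = c("L", "R"),
                               keep_envelopes = FALSE) {
  require_step_channels(rec, sides)
  segments <- segment_recording(rec, config$io$segment_s)
  params <- step_detection_params(config$steps$follow_window_s,
                                  config$steps$diff_threshold,
                                  config$steps$sol_burst_min_s,
                                  config$steps$peak_separation_s)
  all_steps <- list(); all_bursts <- list(); all_thr <- list()
  envs <- list()
  n_ta_bursts <- 0L
  for (seg in segments) {
    seg_env <- list()
    seg_bursts <- list()
    for (s in sides) for (m in c("TA", "Sol")) {
      x <- get_channel(seg, s, m)
      e <- condition(x, seg$rate, config, side = s, muscle = m, t0 = seg$t0)
      thr <- compute_bin_thresholds(e, config)
      b <- detect_bursts(e, thr)
      key <- paste0(s, m)
      seg_env[[key]] <- e
      seg_bursts[[key]] <- b
      thr$side <- s; thr$muscle <- m
      all_thr[[length(all_thr) + 1]] <- thr
      all_bursts[[length(all_bursts) + 1]] <- b
    }
    for (s in sides) {
      ta <- seg_env[[paste0(s, "TA")]]
      sol <- seg_env[[paste0(s, "Sol")]]
      nrm <- normalize_pair(ta, sol)
      d <- relative_difference(nrm$ta, nrm$sol, seg$rate, side = s,
                               t0 = seg$t0)
      st <- detect_steps(d, seg_bursts[[paste0(s, "TA")]],
                         seg_bursts[[paste0(s, "Sol")]], params)
      n_ta_bursts <- n_ta_bursts + nrow(seg_bursts[[paste0(s, "TA")]])
      all_steps[[length(all_steps) + 1]] <- st
    }
    if (keep_envelopes) envs[[length(envs) + 1]] <- seg_env
  }
  steps <- do.call(rbind, all_steps)
  steps <- steps[order(steps$peak_time_s), , drop = FALSE]
  rownames(steps) <- NULL
  out <- list(
    steps = steps,
    bursts = do.call(rbind, all_bursts),
    thresholds = do.call(rbind, all_thr),
    non_step_ta_bursts = n_ta_bursts - nrow(steps),
    duration_s = ncol(rec$samples) / rec$rate,
    config = config
  )
  if (keep_envelopes) out$envelopes <- envs
  structure(out, class = "tokeda_result")
}

#' @export
print.tokeda_result <- function(x, ...) {
  cat(sprintf("<tokeda_result> %.1f s processed: %d step event(s), %d burst(s)\n",
              x$duration_s, nrow(x$steps), nrow(x$bursts)))
  cat(sprintf("  non-step flexor bursts: %d\n", x$non_step_ta_bursts))
  invisible(x)
}

#' Extract MEP features during detected step cycles
#'
#' Band-passes the requested channel, segments stimulation-locked epochs
#' restricted to the detected step-cycle windows, and returns the per-epoch
#' feature table.
#'
#' @param rec an [emg_recording()].
#' @param pulses a [stim_pulse_log()].
#' @param steps step-event data.frame (e.g. `run_step_detection(rec)$steps`);
#'   `NULL` segments every pulse.
#' @param side,muscle channel role to analyse (default right soleus, the
#'   muscle whose evoked responses track the trained task).
#' @param config configuration list.
#' @return data.frame from [mep_feature_table()].
#' @export
run_mep_extraction <- function(rec, pulses, steps = NULL, side = "R",
                               muscle = "Sol", config = tokeda_config()) {
  x <- get_channel(rec, side, muscle)
  cc <- config$conditioning
  bp <- bandpass(x, rec$rate, cc$bandpass_low, cc$bandpass_high,
                 cc$bandpass_order)
  if (!is.null(steps) && nrow(steps))
    steps <- steps[steps$side == side, , drop = FALSE]
  meps <- segment_meps(bp, rec$rate, pulses, steps,
                       epoch_s = config$mep$epoch_s, t0 = rec$t0)
  mep_feature_table(meps, config, side = side, muscle = muscle)
}
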