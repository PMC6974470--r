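#' Simulation configuration
#'
#' Study conditions for the synthetic EMG generator. Defaults mirror the
#' recording setup the detector targets: 10 kHz sampling, 40 Hz / 0.2 ms
#' sub-threshold stimulation, ~2 s stance periods, burst-to-rest amplitude
#' ratio (SNR) of 10, and bout start times drawn from an exponentially
#' time-decaying intensity (activity concentrated early in the session).
#' Non-functional (standing-like) events are tonic extensor activity with
#' weak flexor co-activation. The seed fixes the full sample path.
#'
#' @param rate sampling rate, Hz.
#' @param duration_s total recording length, s.
#' @param n_step_bouts number of stepping bouts.
#' @param steps_per_bout steps per bout.
#' @param swing_s,stance_s swing (flexor burst) and stance (extensor burst)
#'   durations per step, s.
#' @param inter_step_gap_s quiet gap between consecutive steps, s.
#' @param burst_amp_mV RMS amplitude of burst texture, mV.
#' @param rest_noise_mV standard deviation of baseline Gaussian noise, mV.
#' @param co_activation flexor amplitude fraction during non-functional
#'   (standing-like) events.
#' @param n_nonfunctional number of non-functional events.
#' @param nonfunctional_s duration of each non-functional event, s.
#' @param stim add stimulation artifacts and evoked templates?
#' @param stim_rate stimulation rate, Hz.
#' @param stim_pulse_width_s pulse width, s.
#' @param stim_artifact_mV artifact amplitude on the EMG channels, mV.
#' @param mep_amp_mV peak amplitude of the evoked template during step
#'   activity, mV; small relative to bursts by default, as sub-threshold
#'   stimulation evokes (scaled to 20% outside step windows).
#' @param mep_lobes evoked-waveform lobe table, see [default_mep_lobes()].
#' @param activity_decay_halflife_s half-life of the exponential bout
#'   intensity, s.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rate = 10000, duration_s = 900, n_step_bouts = 36,
                       steps_per_bout = 6, swing_s = 0.5, stance_s = 2,
                       inter_step_gap_s = 0.25, burst_amp_mV = 0.5,
                       rest_noise_mV = 0.05, co_activation = 0.2,
                       n_nonfunctional = 5, nonfunctional_s = 3,
                       stim = TRUE, stim_rate = 40,
                       stim_pulse_width_s = 2e-4, stim_artifact_mV = 0.2,
                       mep_amp_mV = 0.1, mep_lobes = default_mep_lobes(),
                       activity_decay_halflife_s = 7200, seed = 1) {
  cfg <- list(rate = rate, duration_s = duration_s,
              n_step_bouts = n_step_bouts, steps_per_bout = steps_per_bout,
              swing_s = swing_s, stance_s = stance_s,
              inter_step_gap_s = inter_step_gap_s,
              burst_amp_mV = burst_amp_mV, rest_noise_mV = rest_noise_mV,
              co_activation = co_activation,
              n_nonfunctional = n_nonfunctional,
              nonfunctional_s = nonfunctional_s,
              stim = stim, stim_rate = stim_rate,
              stim_pulse_width_s = stim_pulse_width_s,
              stim_artifact_mV = stim_artifact_mV,
              mep_amp_mV = mep_amp_mV, mep_lobes = mep_lobes,
              activity_decay_halflife_s = activity_decay_halflife_s,
              seed = seed)
  durs <- c(rate, duration_s, swing_s, stance_s, inter_step_gap_s,
            nonfunctional_s, activity_decay_halflife_s)
  if (any(durs <= 0)) stop("rates and durations must be > 0")
  structure(cfg, class = "sim_config")
}

#' Default evoked-waveform lobe table
#'
#' Gaussian lobes composing the synthetic evoked potential, with one early
#' (2.5 ms), one middle (5 ms) and three late (10, 14, 19 ms) components.
#' Lobe centres fall on the 10 kHz sample grid, so extremum times and
#' amplitudes are known analytically: the peak curvature of a lobe of
#' amplitude `a` (mV) and width `s` (ms) is `a / (s/1000)^2` mV/s^2 and its
#' prominence on a quiet baseline is `|a|`.
#'
#' @return data.frame with `t_ms`, `amp_mV`, `width_ms`.
#' @export
default_mep_lobes <- function() {
  data.frame(
    t_ms = c(2.5, 5, 10, 14, 19),
    amp_mV = c(0.5, 0.6, 0.6, -0.5, 0.45),
    width_ms = c(0.3, 0.4, 0.5, 0.5, 0.45)
  )
}

# sampled evoked template over one epoch, unit-normalized peak amplitude
mep_template <- function(lobes, rate, epoch_s = 0.025) {
  n <- round(epoch_s * rate)
  t_ms <- (seq_len(n) - 1) / rate * 1000
  y <- numeric(n)
  for (k in seq_len(nrow(lobes))) {
    y <- y + lobes$amp_mV[k] *
      exp(-(t_ms - lobes$t_ms[k])^2 / (2 * lobes$width_ms[k]^2))
  }
  m <- max(abs(y))
  if (m > 0) y / m else y
}

# band-limited (30-400 Hz) unit-RMS noise texture with raised-cosine edges
burst_texture <- function(len, rate, ramp_s = 0.05) {
  pad <- min(len, 400L)
  bf <- signal::butter(3, c(30, 400) / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(len + 2 * pad))
  x <- x[(pad + 1):(pad + len)]
  x <- x / stats::sd(x)
  nr <- min(round(ramp_s * rate), len %/% 4)
  if (nr > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    x[1:nr] <- x[1:nr] * ramp
    x[(len - nr + 1):len] <- x[(len - nr + 1):len] * rev(ramp)
  }
  x
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a multi-channel EMG recording with ground truth
#'
#' Generates four channels (LTA, RTA, LSol, RSol): Gaussian rest baseline,
#' amplitude-modulated band-limited (30-400 Hz) noise bursts on the flexor
#' channel during swing and on the extensor channel during stance of each
#' scheduled step, stimulation pulse artifacts plus scaled evoked templates
#' at the stimulation rate, and standing-like non-functional events (tonic
#' extensor burst, weak flexor co-activation). Bout start times follow an
#' exponentially decaying intensity over the session; bouts alternate
#' sides. EMG texture is modelled at the envelope level only (no
#' motor-unit structure), which is all the burst detector observes.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (an [emg_recording()]), `truth`
#'   (annotation data.frame: `label`, `side`, `onset_s`, `offset_s`) and
#'   `pulses` (a [stim_pulse_log()], empty when `cfg$stim` is `FALSE`).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    rate <- cfg$rate
    N <- round(cfg$duration_s * rate)
    ch_names <- c("LTA", "RTA", "LSol", "RSol")
    X <- matrix(stats::rnorm(4 * N, sd = cfg$rest_noise_mV), nrow = 4)
    step_s <- cfg$swing_s + cfg$stance_s + cfg$inter_step_gap_s
    bout_len <- cfg$steps_per_bout * step_s
    min_gap <- 2
    events <- list()
    bouts <- data.frame(start = numeric(0), end = numeric(0))

    add_burst <- function(ch, t_on, dur, amp) {
      i0 <- round(t_on * rate) + 1
      len <- round(dur * rate)
      i1 <- min(i0 + len - 1, N)
      if (i1 <= i0) return(invisible(NULL))
      seg <- burst_texture(i1 - i0 + 1, rate)
      X[ch, i0:i1] <<- X[ch, i0:i1] + amp * seg
      invisible(NULL)
    }

    if (cfg$n_step_bouts > 0) {
      tau <- cfg$activity_decay_halflife_s / log(2)
      u <- sort(stats::runif(cfg$n_step_bouts))
      raw <- -tau * log(1 - u * (1 - exp(-cfg$duration_s / tau)))
      prev_end <- 0
      truncated <- FALSE
      for (b in seq_along(raw)) {
        start <- max(raw[b], prev_end + min_gap)
        n_fit <- floor((cfg$duration_s - 0.5 - start) / step_s)
        n_steps <- min(cfg$steps_per_bout, max(n_fit, 0))
        if (n_steps < cfg$steps_per_bout) truncated <- TRUE
        if (n_steps <= 0) next
        side <- if (b %% 2 == 1) "L" else "R"
        ta_ch <- if (side == "L") 1 else 2
        sol_ch <- if (side == "L") 3 else 4
        for (k in seq_len(n_steps)) {
          t_sw <- start + (k - 1) * step_s
          add_burst(ta_ch, t_sw, cfg$swing_s, cfg$burst_amp_mV)
          add_burst(sol_ch, t_sw + cfg$swing_s, cfg$stance_s,
                    cfg$burst_amp_mV)
          events[[length(events) + 1]] <- data.frame(
            label = "step", side = side, onset_s = t_sw,
            offset_s = t_sw + cfg$swing_s + cfg$stance_s,
            stringsAsFactors = FALSE)
        }
        end <- start + n_steps * step_s
        bouts <- rbind(bouts, data.frame(start = start, end = end))
        prev_end <- end
      }
      if (truncated)
        warning("bout schedule exceeded the recording; truncated")
    }

    # standing-like non-functional events in the remaining quiet time
    placed <- bouts
    for (k in seq_len(cfg$n_nonfunctional)) {
      for (try in 1:200) {
        t0 <- stats::runif(1, 1, cfg$duration_s - cfg$nonfunctional_s - 1)
        t1 <- t0 + cfg$nonfunctional_s
        clash <- nrow(placed) > 0 &&
          any(placed$start < t1 + min_gap & placed$end > t0 - min_gap)
        if (!clash) {
          side <- if (k %% 2 == 1) "R" else "L"
          ta_ch <- if (side == "L") 1 else 2
          sol_ch <- if (side == "L") 3 else 4
          add_burst(sol_ch, t0, cfg$nonfunctional_s, cfg$burst_amp_mV)
          add_burst(ta_ch, t0, cfg$nonfunctional_s,
                    cfg$co_activation * cfg$burst_amp_mV)
          events[[length(events) + 1]] <- data.frame(
            label = "non_functional", side = side, onset_s = t0,
            offset_s = t1, stringsAsFactors = FALSE)
          placed <- rbind(placed, data.frame(start = t0, end = t1))
          break
        }
      }
    }

    pulses <- stim_pulse_log(numeric(0), cfg$stim_rate,
                             cfg$stim_pulse_width_s)
    if (cfg$stim) {
      period <- 1 / cfg$stim_rate
      ends <- seq(period, cfg$duration_s - 0.001, by = period)
      wid <- max(1L, round(cfg$stim_pulse_width_s * rate))
      tmpl <- mep_template(cfg$mep_lobes, rate)
      n_t <- length(tmpl)
      step_ev <- if (length(events)) do.call(rbind, events) else
        data.frame(label = character(0), side = character(0),
                   onset_s = numeric(0), offset_s = numeric(0))
      step_ev <- step_ev[step_ev$label == "step", , drop = FALSE]
      in_step <- list(L = rep(FALSE, length(ends)),
                      R = rep(FALSE, length(ends)))
      for (s in c("L", "R")) {
        se <- step_ev[step_ev$side == s, , drop = FALSE]
        if (nrow(se)) {
          idx <- findInterval(ends, se$onset_s)
          in_step[[s]] <- idx >= 1 & ends < se$offset_s[pmax(idx, 1)]
        }
      }
      for (p in seq_along(ends)) {
        iend <- round(ends[p] * rate)
        art <- max(1, iend - wid + 1):iend
        X[, art] <- X[, art] + cfg$stim_artifact_mV
        i0 <- iend + 1
        i1 <- min(i0 + n_t - 1, N)
        if (i1 < i0) next
        for (s in c("L", "R")) {
          amp <- if (in_step[[s]][p]) cfg$mep_amp_mV else 0.2 * cfg$mep_amp_mV
          chs <- if (s == "L") c(1, 3) else c(2, 4)
          X[chs, i0:i1] <- X[chs, i0:i1] +
            rep(amp * tmpl[seq_len(i1 - i0 + 1)], each = 2)
        }
      }
      pulses <- stim_pulse_log(ends, cfg$stim_rate, cfg$stim_pulse_width_s)
    }

    truth <- if (length(events)) {
      validate_annotations(do.call(rbind, events))
    } else {
      data.frame(label = character(0), side = character(0),
                 onset_s = numeric(0), offset_s = numeric(0),
                 stringsAsFactors = FALSE)
    }
    list(recording = emg_recording(X, rate, ch_names),
         truth = truth, pulses = pulses)
  })
}

#' Simulate a train of evoked-potential epochs with known extrema
#'
#' Builds `n_epochs` consecutive 25 ms epochs, each the sampled lobe
#' template (optionally plus band-limited noise), together with the
#' analytically known extremum list: time, amplitude, response window, and
#' whether each lobe is expected to survive the detector's prominence and
#' curvature filters at the given thresholds.
#'
#' @param n_epochs number of epochs.
#' @param rate sampling rate, Hz.
#' @param lobes lobe table, see [default_mep_lobes()]; `amp_mV` is used
#'   as-is (no unit normalization here).
#' @param noise_mV standard deviation of added band-limited noise (0 for a
#'   clean train).
#' @param epoch_s epoch length, s.
#' @param min_prominence,d2_threshold detector thresholds used to compute
#'   the `expected_detected` flag.
#' @param seed RNG seed (used when `noise_mV > 0`).
#' @return list with `signal` (numeric vector), `rate`, `epoch_s`,
#'   `truth` (data.frame: `t_ms`, `amp_mV`, `type`, `window`,
#'   `expected_detected`) describing each lobe of every epoch's template.
#' @export
simulate_mep_train <- function(n_epochs, rate = 10000,
                               lobes = default_mep_lobes(), noise_mV = 0,
                               epoch_s = 0.025, min_prominence = 0.2,
                               d2_threshold = 1.5e6, seed = 1) {
  n_ep <- round(epoch_s * rate)
  base <- numeric(n_ep)
  t_ms <- (seq_len(n_ep) - 1) / rate * 1000
  for (k in seq_len(nrow(lobes))) {
    base <- base + lobes$amp_mV[k] *
      exp(-(t_ms - lobes$t_ms[k])^2 / (2 * lobes$width_ms[k]^2))
  }
  signal <- rep(base, n_epochs)
  if (noise_mV > 0) {
    # noise occupies the 30-1000 Hz recording band: real epochs are cut
    # from band-pass-filtered EMG, so wider-band noise cannot reach them
    signal <- with_seed(seed, {
      bf <- signal::butter(3, c(30, 1000) / (rate / 2), type = "pass")
      nz <- signal::filtfilt(bf, stats::rnorm(length(signal)))
      signal + noise_mV * nz / stats::sd(nz)
    })
  }
  win_of <- function(t) {
    if (t >= 1 && t < 4) "ER" else if (t >= 4 && t < 7) "MR"
    else if (t >= 7 && t < 25) "LR" else "artifact"
  }
  truth <- data.frame(
    t_ms = lobes$t_ms, amp_mV = lobes$amp_mV,
    type = ifelse(lobes$amp_mV >= 0, "peak", "trough"),
    window = vapply(lobes$t_ms, win_of, ""),
    curvature = abs(lobes$amp_mV) / (lobes$width_ms / 1000)^2,
    stringsAsFactors = FALSE
  )
  truth$expected_detected <- abs(truth$amp_mV) >= min_prominence &
    truth$curvature >= d2_threshold
  list(signal = signal, rate = rate, epoch_s = epoch_s, truth = truth)
}
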