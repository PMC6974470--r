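#' Stimulation-locked MEP epoch
#'
#' One 25 ms motor-evoked-potential epoch cut from band-pass-filtered EMG at
#' the end of a stimulation pulse. Response windows relative to the epoch
#' start: early response (ER) 1-4 ms, middle response (MR) 4-7 ms, late
#' response (LR) 7-25 ms (half-open). The MR and LR are commonly read as
#' mono- and polysynaptic pathway markers. Peaks earlier than 1 ms are
#' attributed to stimulation artifact and never counted.
#'
#' @param samples numeric vector (mV), `round(epoch_s * rate)` samples.
#' @param rate sampling rate in Hz.
#' @param start_s epoch start (pulse end time) in recording seconds.
#' @param epoch_s epoch length in seconds (default 0.025).
#' @return object of class `mep_window` with empty `peaks`/`troughs`.
#' @export
mep_window <- function(samples, rate, start_s = 0, epoch_s = 0.025) {
  n_expect <- round(epoch_s * rate)
  if (length(samples) != n_expect)
    stop("epoch must have ", n_expect, " samples at ", rate, " Hz")
  structure(list(samples = as.numeric(samples), rate = rate,
                 start_s = start_s, epoch_s = epoch_s,
                 peaks = NULL, troughs = NULL),
            class = "mep_window")
}

#' Segment band-passed EMG into stimulation-locked MEP epochs
#'
#' Cuts one `epoch_s` (25 ms) epoch starting at the end of each stimulation
#' pulse. With 40 Hz stimulation at 10 kHz the epochs are consecutive
#' 250-sample windows that tile the record with no gap or overlap. When
#' step events are supplied, only epochs lying fully inside some step cycle
#' `[swing_start, stance_end]` are kept; epochs running past the end of the
#' recording are dropped.
#'
#' @param x band-pass-filtered EMG vector (mV); see [bandpass()]. MEPs are
#'   taken from the band-passed trace, not from the energy envelope.
#' @param rate sampling rate in Hz; `rate * epoch_s` must be >= 25 samples.
#' @param pulses a [stim_pulse_log()].
#' @param steps optional step-event data.frame from [detect_steps()]; when
#'   `NULL` or empty every pulse is segmented and the result carries
#'   attribute `restricted = FALSE`.
#' @param epoch_s epoch length in seconds.
#' @param t0 start offset of `x` in recording seconds.
#' @return list of [mep_window()] objects, attribute `restricted` marking
#'   whether step gating was applied.
#' @export
segment_meps <- function(x, rate, pulses, steps = NULL, epoch_s = 0.025,
                         t0 = 0) {
  n_ep <- round(epoch_s * rate)
  if (n_ep < 25) stop("rate too low: need at least 25 samples per epoch")
  n <- length(x)
  eps <- 0.5 / rate
  times <- pulses$pulse_end_times
  restricted <- !is.null(steps) && nrow(steps) > 0
  if (restricted) {
    ok <- vapply(times, function(t) {
      any(t >= steps$swing_start_s - eps &
            t + epoch_s <= steps$stance_end_s + eps)
    }, logical(1))
    times <- times[ok]
  }
  out <- list()
  for (t in times) {
    i0 <- floor((t - t0) * rate + 1e-9) + 1
    i1 <- i0 + n_ep - 1
    if (i0 < 1 || i1 > n) next  # epoch at recording edge: dropped
    out[[length(out) + 1]] <- mep_window(x[i0:i1], rate, start_s = t,
                                         epoch_s = epoch_s)
  }
  attr(out, "restricted") <- restricted
  out
}

# topographic prominence of extremum `i` of `y` (maxima; pass -y for minima)
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i
  while (j > 1) {
    j <- j - 1
    if (y[j] > y[i]) break
    if (y[j] < left_min) left_min <- y[j]
  }
  if (y[j] <= y[i]) left_min <- min(left_min, y[j])
  right_min <- y[i]; j <- i
  while (j < n) {
    j <- j + 1
    if (y[j] > y[i]) break
    if (y[j] < right_min) right_min <- y[j]
  }
  if (y[j] <= y[i]) right_min <- min(right_min, y[j])
  y[i] - max(left_min, right_min)
}

#' Detect MEP peaks and troughs
#'
#' The epoch is interpolated to double the number of points (piecewise
#' cubic by default); local maxima and minima of the interpolated trace are
#' kept subject to three filters:
#' \enumerate{
#'   \item minimum topographic prominence `min_prominence` (mV);
#'   \item minimum separation `min_separation_ms` between extrema of the
#'     same type (larger amplitude wins);
#'   \item second-differential magnitude `|y''| >= d2_threshold` (mV/s^2,
#'     central differences on the interpolated grid).
#' }
#' The curvature constant is sampling-dependent: it is stored together with
#' the rate it assumes (`d2_assumed_rate`) and rescaled by
#' `(rate / d2_assumed_rate)^2`, with a warning, when the epoch was sampled
#' at a different rate.
#'
#' @param mep a [mep_window()].
#' @param min_separation_ms minimum same-type extremum spacing (default 0.6).
#' @param min_prominence minimum prominence in mV (default 0.2).
#' @param d2_threshold curvature threshold (default 1.5e6 mV/s^2 at 10 kHz).
#' @param d2_assumed_rate sampling rate at which `d2_threshold` applies.
#' @param interp `"cubic"` (default) or `"linear"` interpolation.
#' @return the `mep_window` with `peaks` and `troughs` filled: data.frames
#'   with `time_ms` (on the original epoch time base) and `amplitude_mV`.
#' @export
detect_mep_extrema <- function(mep, min_separation_ms = 0.6,
                               min_prominence = 0.2, d2_threshold = 1.5e6,
                               d2_assumed_rate = 10000,
                               interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  rate <- mep$rate
  if (rate != d2_assumed_rate) {
    d2_threshold <- d2_threshold * (rate / d2_assumed_rate)^2
    warning(sprintf(
      "curvature threshold rescaled to %.3g mV/s^2 for %g Hz sampling",
      d2_threshold, rate))
  }
  y0 <- mep$samples
  n <- length(y0)
  dt <- 1 / rate
  t_orig <- (seq_len(n) - 1) * dt
  tt <- seq(0, t_orig[n], by = dt / 2)
  y <- if (interp == "cubic") {
    stats::spline(t_orig, y0, xout = tt, method = "fmm")$y
  } else {
    stats::approx(t_orig, y0, xout = tt)$y
  }
  h <- dt / 2
  m <- length(y)
  pick <- function(yy, sign) {
    # sign = +1 for peaks on yy, -1 evaluates minima via -yy
    z <- sign * yy
    idx <- local_maxima(z)
    if (!length(idx)) return(idx)
    prom <- vapply(idx, function(i) peak_prominence(z, i), numeric(1))
    idx <- idx[prom >= min_prominence - 1e-12]
    if (!length(idx)) return(idx)
    # enforce minimum separation, larger amplitude first (ties: earlier)
    ord <- order(-z[idx], idx)
    kept <- integer(0)
    min_sep <- min_separation_ms * 1e-3
    for (i in idx[ord]) {
      if (!length(kept) || all(abs(tt[kept] - tt[i]) >= min_sep - 1e-12))
        kept <- c(kept, i)
    }
    kept <- sort(kept)
    # curvature filter on the interpolated grid
    d2 <- (y[kept - 1] - 2 * y[kept] + y[kept + 1]) / h^2
    kept[abs(d2) >= d2_threshold]
  }
  pk <- pick(y, +1)
  tr <- pick(y, -1)
  mep$peaks <- data.frame(time_ms = tt[pk] * 1e3, amplitude_mV = y[pk])
  mep$troughs <- data.frame(time_ms = tt[tr] * 1e3, amplitude_mV = y[tr])
  mep
}

# 0-based sample index range [a_ms, b_ms) -> inclusive 1-based trapezoid
# endpoints on the epoch grid, sharing the boundary sample between windows
window_grid <- function(a_ms, b_ms, rate, n) {
  ka <- ceiling(a_ms * rate / 1000 - 1e-9)
  kb <- min(floor(b_ms * rate / 1000 + 1e-9), n - 1)
  c(ka + 1L, kb + 1L)
}

#' Extract features from one MEP epoch
#'
#' Integrated EMG (trapezoidal integral of the rectified trace, mV*ms) over
#' the MR and LR windows, peak-to-peak amplitude over the whole epoch, and
#' the number of retained peaks falling in each of the ER/MR/LR windows.
#' The MR and LR integrals share the 7 ms boundary sample, so their sum
#' equals the integral over the joint 4-25 ms window.
#'
#' @param mep a [mep_window()] with extrema detected by
#'   [detect_mep_extrema()].
#' @param er_ms,mr_ms,lr_ms window bounds in ms (half-open).
#' @return one-row data.frame: `start_s`, `iemg_mr`, `iemg_lr`,
#'   `peak_to_peak`, `n_peaks_er`, `n_peaks_mr`, `n_peaks_lr`,
#'   `n_troughs`.
#' @export
mep_features <- function(mep, er_ms = c(1, 4), mr_ms = c(4, 7),
                         lr_ms = c(7, 25)) {
  if (is.null(mep$peaks))
    stop("detect extrema first (detect_mep_extrema)")
  y <- abs(mep$samples)
  n <- length(y)
  rate <- mep$rate
  dt_ms <- 1000 / rate
  iemg <- function(w) {
    g <- window_grid(w[1], w[2], rate, n)
    if (g[2] <= g[1]) return(0)
    pracma::trapz(seq(g[1], g[2]) * dt_ms, y[g[1]:g[2]])
  }
  count_in <- function(w) sum(mep$peaks$time_ms >= w[1] &
                                mep$peaks$time_ms < w[2])
  data.frame(
    start_s = mep$start_s,
    iemg_mr = iemg(mr_ms), iemg_lr = iemg(lr_ms),
    peak_to_peak = max(mep$samples) - min(mep$samples),
    n_peaks_er = count_in(er_ms), n_peaks_mr = count_in(mr_ms),
    n_peaks_lr = count_in(lr_ms),
    n_troughs = nrow(mep$troughs)
  )
}

#' Feature table over a list of MEP epochs
#'
#' Runs [detect_mep_extrema()] and [mep_features()] over every epoch.
#'
#' @param meps list of [mep_window()] from [segment_meps()].
#' @param config configuration list, see [tokeda_config()].
#' @param side,muscle optional labels added to the table.
#' @return data.frame, one row per epoch.
#' @export
mep_feature_table <- function(meps, config = tokeda_config(),
                              side = NA_character_, muscle = NA_character_) {
  mc <- config$mep
  rows <- lapply(meps, function(m) {
    m <- detect_mep_extrema(m, mc$min_separation_ms, mc$min_prominence,
                            mc$d2_threshold, mc$d2_assumed_rate, mc$interp)
    mep_features(m, mc$er_ms, mc$mr_ms, mc$lr_ms)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start_s = numeric(0), iemg_mr = numeric(0),
                      iemg_lr = numeric(0), peak_to_peak = numeric(0),
                      n_peaks_er = integer(0), n_peaks_mr = integer(0),
                      n_peaks_lr = integer(0), n_troughs = integer(0))
  }
  out$side <- side
  out$muscle <- muscle
  out
}

#' Treatment-vs-baseline summary of MEP peak counts
#'
#' Total late- and middle-response peak counts of a treatment feature table
#' expressed as a ratio to the baseline (Pre) totals.
#'
#' @param features treatment feature table from [mep_feature_table()].
#' @param reference baseline feature table (non-empty).
#' @return list with `lr_ratio` and `mr_ratio` (`NA` when the corresponding
#'   baseline total is zero).
#' @export
mep_response_summary <- function(features, reference) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("reference feature table must be non-empty")
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(
    lr_ratio = ratio(sum(features$n_peaks_lr), sum(reference$n_peaks_lr)),
    mr_ratio = ratio(sum(features$n_peaks_mr), sum(reference$n_peaks_mr))
  )
}
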