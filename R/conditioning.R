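#' EMG activity envelope
#'
#' Container for the conditioned activity trace produced by [condition()]:
#' band-passed, passed through the Teager-Kaiser energy operator, rectified
#' and low-pass smoothed. Values are instantaneous-energy estimates on a
#' mV^2 scale and are non-negative by construction.
#'
#' @param values non-negative numeric vector.
#' @param rate sampling rate in Hz.
#' @param side,muscle source-channel role (optional).
#' @param t0 start offset in seconds.
#' @return object of class `envelope`.
#' @export
envelope <- function(values, rate, side = NA_character_,
                     muscle = NA_character_, t0 = 0) {
  stopifnot(rate > 0)
  structure(list(values = as.numeric(values), rate = rate, side = side,
                 muscle = muscle, t0 = t0),
            class = "envelope")
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %s%s: %.3f s @ %g Hz, mean %.3g\n",
              ifelse(is.na(x$side), "", x$side),
              ifelse(is.na(x$muscle), "?", x$muscle),
              length(x$values) / x$rate, x$rate, mean(x$values)))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth band-pass (30-1000 Hz by default) applied
#' forward-backward with [signal::filtfilt()], so event timing is not
#' distorted by filter phase. Attenuates DC offset and high-frequency noise.
#'
#' @param x numeric vector (mV).
#' @param rate sampling rate in Hz.
#' @param low,high cut-off frequencies in Hz; must satisfy
#'   `0 < low < high < rate/2`.
#' @param order filter order (per band edge).
#' @return filtered vector, same length as `x`.
#' @export
bandpass <- function(x, rate, low = 30, high = 1000, order = 3) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= rate / 2) stop("high cut-off must be below the Nyquist rate")
  bf <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Teager-Kaiser energy operator
#'
#' `psi[n] = x[n]^2 - x[n-1] * x[n+1]` for interior samples; the endpoints
#' copy the nearest interior value so the output has the same length as the
#' input. For a sinusoid `A*sin(Omega*n + phi)` the interior output is the
#' constant `A^2 * sin(Omega)^2`, which makes the operator an
#' amplitude-and-frequency-weighted instantaneous energy estimate that
#' sharpens burst onsets.
#'
#' @param x numeric vector, length >= 3.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' tkeo(c(1, 2, 3))   # interior value: 4 - 1*3 = 1
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) stop("tkeo needs at least 3 samples")
  psi <- numeric(n)
  psi[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  psi[1] <- psi[2]
  psi[n] <- psi[n - 1]
  psi
}

#' Rectify and low-pass smooth into an envelope
#'
#' Absolute value followed by a zero-phase low-pass Butterworth filter
#' (50 Hz cut-off, order 3 by default); small negative post-filter ripple is
#' clipped to zero so the envelope is non-negative everywhere.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param cutoff low-pass cut-off in Hz (< `rate/2`).
#' @param order filter order.
#' @param side,muscle,t0 passed to [envelope()].
#' @return an [envelope()].
#' @export
rectify_smooth <- function(x, rate, cutoff = 50, order = 3,
                           side = NA_character_, muscle = NA_character_,
                           t0 = 0) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist rate")
  lf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  y <- signal::filtfilt(lf, abs(x))
  envelope(pmax(y, 0), rate, side, muscle, t0)
}

#' Condition raw EMG into an activity envelope
#'
#' Full conditioning chain: [bandpass()] -> [tkeo()] -> [rectify_smooth()].
#' Because the energy operator is quadratic and the filters linear, the
#' chain is scale-equivariant: `condition(k * x)` equals
#' `k^2 * condition(x)` for `k > 0` up to filter round-off.
#'
#' @param x numeric vector of raw EMG (mV).
#' @param rate sampling rate in Hz.
#' @param config configuration list, see [tokeda_config()].
#' @param side,muscle,t0 channel metadata carried on the envelope.
#' @return an [envelope()] (values on a mV^2 scale).
#' @export
condition <- function(x, rate, config = tokeda_config(),
                      side = NA_character_, muscle = NA_character_, t0 = 0) {
  cc <- config$conditioning
  bp <- bandpass(x, rate, cc$bandpass_low, cc$bandpass_high, cc$bandpass_order)
  rectify_smooth(tkeo(bp), rate, cc$smooth_cutoff, cc$smooth_order,
                 side = side, muscle = muscle, t0 = t0)
}
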