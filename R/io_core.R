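#' Multi-channel EMG recording container
#'
#' Lightweight S3 container for a chronically recorded multi-channel EMG
#' trace. Channel roles are resolved from channel names of the form
#' `"LTA"`, `"RTA"`, `"LSol"`, `"RSol"` (side `L`/`R` x muscle `TA`/`Sol`);
#' unknown names are kept but carry no role and cannot participate in step
#' detection.
#'
#' Time convention: sample `i` (1-based) covers the half-open interval
#' `[t0 + (i-1)/rate, t0 + i/rate)` seconds; its point value is timestamped
#' at the interval start. All event intervals in the package are half-open
#' `[onset, offset)`.
#'
#' @param samples numeric matrix, channels x time, in mV.
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of channel names (one per row of
#'   `samples`).
#' @param t0 recording start offset in seconds.
#' @return object of class `emg_recording` with fields `samples`, `rate`,
#'   `channels` (data.frame `name`, `side`, `muscle`) and `t0`.
#' @export
#' @examples
#' x <- matrix(rnorm(4000), nrow = 4)
#' rec <- emg_recording(x, rate = 1000, channels = c("LTA", "RTA", "LSol", "RSol"))
#' rec
emg_recording <- function(samples, rate, channels, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(rate), length(rate) == 1)
  if (rate <= 0) stop("rate must be > 0")
  if (length(channels) != nrow(samples))
    stop("need one channel name per row of samples")
  roles <- parse_channel_roles(channels)
  structure(
    list(samples = samples, rate = rate, channels = roles, t0 = t0),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channel(s) x %.3f s @ %g Hz (t0 = %g s)\n",
    nrow(x$samples), ncol(x$samples) / x$rate, x$rate, x$t0
  ))
  cat("  channels:", paste(x$channels$name, collapse = ", "), "\n")
  invisible(x)
}

#' Parse channel names into side/muscle roles
#'
#' @param names character vector such as `c("LTA", "RSol")`.
#' @return data.frame with columns `name`, `side` (`"L"`/`"R"`/`NA`) and
#'   `muscle` (`"TA"`/`"Sol"`/`NA`).
#' @export
parse_channel_roles <- function(names) {
  m <- regmatches(names, regexec("^([LlRr])[ _-]?(TA|ta|Ta|SOL|Sol|sol)$", names))
  side <- vapply(m, function(g) if (length(g)) toupper(g[2]) else NA_character_, "")
  muscle <- vapply(m, function(g) {
    if (!length(g)) return(NA_character_)
    if (toupper(g[3]) == "TA") "TA" else "Sol"
  }, "")
  data.frame(name = as.character(names), side = side, muscle = muscle,
             stringsAsFactors = FALSE)
}

#' Extract one channel by role
#'
#' @param rec an [emg_recording()].
#' @param side `"L"` or `"R"`.
#' @param muscle `"TA"` or `"Sol"`.
#' @return numeric vector of samples (mV).
#' @export
get_channel <- function(rec, side, muscle) {
  i <- which(rec$channels$side == side & rec$channels$muscle == muscle)
  if (length(i) == 0)
    stop("missing ", if (muscle == "Sol") "extensor" else "flexor",
         " channel: ", side, muscle)
  if (length(i) > 1)
    stop("more than one channel maps to ", side, muscle)
  rec$samples[i, ]
}

#' Check that a recording carries the four channels step detection needs
#'
#' Step detection requires exactly one channel per (side, muscle) pair for
#' the sides requested. Corrupted/absent channels are never imputed; this
#' fails loudly instead.
#'
#' @param rec an [emg_recording()].
#' @param sides sides to check, default both.
#' @return invisibly `TRUE`; error naming the first missing channel otherwise.
#' @export
require_step_channels <- function(rec, sides = c("L", "R")) {
  for (s in sides) for (m in c("TA", "Sol")) {
    n <- sum(rec$channels$side == s & rec$channels$muscle == m, na.rm = TRUE)
    if (n == 0)
      stop("missing ", if (m == "Sol") "extensor" else "flexor",
           " channel: ", s, m)
    if (n > 1) stop("duplicate channel role: ", s, m)
  }
  invisible(TRUE)
}

#' Read an EMG recording
#'
#' Supported dialects: delimited text with a header row naming the channels
#' (one column per channel), and multi-channel RIFF/WAV (16-bit PCM with an
#' explicit mV-per-unit scale, or 32-bit float taken as mV unless scaled).
#'
#' @param path input file.
#' @param rate sampling rate in Hz; required for delimited text, read from
#'   the header for WAV.
#' @param format `"auto"` (by extension), `"delim"` or `"wav"`.
#' @param scale_mV mV per integer unit for PCM WAV input.
#' @param channels optional channel names overriding the file header
#'   (required for WAV, which stores none).
#' @param t0 recording start offset in seconds.
#' @return an [emg_recording()].
#' @export
read_emg <- function(path, rate = NULL, format = c("auto", "delim", "wav"),
                     scale_mV = NULL, channels = NULL, t0 = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "delim"
  }
  if (format == "delim") {
    if (is.null(rate)) stop("rate missing: pass `rate` for delimited input")
    df <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE)
    nm <- if (is.null(channels)) names(df) else channels
    emg_recording(unname(t(as.matrix(df))), rate = rate, channels = nm,
                  t0 = t0)
  } else {
    w <- read_wav(path)
    if (is.null(channels))
      stop("WAV input stores no channel names: pass `channels`")
    samp <- w$samples
    if (w$format == "pcm16") {
      if (is.null(scale_mV))
        stop("rate/scale missing: pass `scale_mV` (mV per integer unit) for PCM WAV")
      samp <- samp * scale_mV
    } else if (!is.null(scale_mV)) {
      samp <- samp * scale_mV
    }
    emg_recording(samp, rate = if (is.null(rate)) w$rate else rate,
                  channels = channels, t0 = t0)
  }
}

#' Write an EMG recording
#'
#' @param rec an [emg_recording()].
#' @param path output file.
#' @param format `"delim"` (whitespace-delimited text, header of channel
#'   names) or `"wav"` (32-bit float RIFF, values stored as mV).
#' @return invisibly `path`.
#' @export
write_emg <- function(rec, path, format = c("delim", "wav")) {
  format <- match.arg(format)
  if (format == "delim") {
    df <- as.data.frame(t(rec$samples))
    names(df) <- rec$channels$name
    utils::write.table(df, path, sep = " ", row.names = FALSE, quote = FALSE)
  } else {
    write_wav(rec$samples, rec$rate, path)
  }
  invisible(path)
}

# Minimal RIFF/WAV reader: PCM 16-bit (format code 1) and IEEE float 32-bit
# (format code 3). Returns channels x time matrix.
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAV file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        code = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("incomplete WAV file: ", path)
  if (fmt$code == 1 && fmt$bits == 16) {
    v <- readBin(data_raw, "integer", length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little")
    format <- "pcm16"
  } else if (fmt$code == 3 && fmt$bits == 32) {
    v <- readBin(data_raw, "numeric", length(data_raw) / 4, 4,
                 endian = "little")
    format <- "float32"
  } else {
    stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
  }
  samples <- matrix(v, nrow = fmt$n_channels)  # WAV interleaves frames
  list(samples = samples, rate = fmt$rate, format = format)
}

write_wav <- function(samples, rate, path) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  n_ch <- nrow(samples)
  v <- as.numeric(samples)  # column-major = interleaved frames
  data_bytes <- length(v) * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(3L, con, 2, endian = "little")          # IEEE float
  writeBin(as.integer(n_ch), con, 2, endian = "little")
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * n_ch * 4), con, 4, endian = "little")
  writeBin(as.integer(n_ch * 4), con, 2, endian = "little")
  writeBin(16L + 16L, con, 2, endian = "little")   # 32 bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, 4, endian = "little")
  writeBin(v, con, 4, endian = "little")
  invisible(path)
}

#' Split a long recording into fixed-length processing segments
#'
#' Six-hour recordings are processed in 10-minute segments; a trailing
#' partial segment is kept rather than dropped.
#'
#' @param rec an [emg_recording()].
#' @param segment_s segment length in seconds (default 600).
#' @return list of `emg_recording` objects with `t0` advanced per segment.
#' @export
segment_recording <- function(rec, segment_s = 600) {
  n <- ncol(rec$samples)
  len <- round(segment_s * rec$rate)
  starts <- seq(1, n, by = len)
  lapply(starts, function(i0) {
    i1 <- min(i0 + len - 1, n)
    emg_recording(rec$samples[, i0:i1, drop = FALSE], rec$rate,
                  rec$channels$name, t0 = rec$t0 + (i0 - 1) / rec$rate)
  })
}

#' Stimulation pulse log
#'
#' @param pulse_end_times strictly increasing pulse end times in seconds.
#' @param nominal_rate nominal stimulation rate in Hz (e.g. 40).
#' @param pulse_width pulse width in seconds (e.g. 2e-4).
#' @return object of class `stim_pulse_log`.
#' @export
stim_pulse_log <- function(pulse_end_times, nominal_rate = NA_real_,
                           pulse_width = NA_real_) {
  if (length(pulse_end_times) > 1 && any(diff(pulse_end_times) <= 0))
    stop("pulse_end_times must be strictly increasing")
  structure(list(pulse_end_times = as.numeric(pulse_end_times),
                 nominal_rate = nominal_rate, pulse_width = pulse_width),
            class = "stim_pulse_log")
}

#' @export
print.stim_pulse_log <- function(x, ...) {
  cat(sprintf("<stim_pulse_log> %d pulse(s)", length(x$pulse_end_times)))
  if (!is.na(x$nominal_rate)) cat(sprintf(" @ %g Hz nominal", x$nominal_rate))
  cat("\n")
  invisible(x)
}

#' Check inter-pulse regularity of a pulse log
#'
#' @param log a [stim_pulse_log()] with a known `nominal_rate`.
#' @param tol relative tolerance on inter-pulse gaps (default 0.2 = +/-20%).
#' @return invisibly `TRUE`; error if any gap deviates beyond `tol`.
#' @export
validate_pulse_log <- function(log, tol = 0.2) {
  if (is.na(log$nominal_rate) || length(log$pulse_end_times) < 2)
    return(invisible(TRUE))
  gaps <- diff(log$pulse_end_times)
  expect <- 1 / log$nominal_rate
  bad <- which(abs(gaps - expect) > tol * expect)
  if (length(bad))
    stop(sprintf("inter-pulse gap %d (%.4f s) deviates from nominal %.4f s",
                 bad[1], gaps[bad[1]], expect))
  invisible(TRUE)
}

#' Detect stimulation pulses on a dedicated stimulation channel
#'
#' A pulse is a maximal run of samples with `|value| >= threshold`; runs
#' separated by fewer than 2 sub-threshold samples are merged. The pulse end
#' time is the end of the last sample of the run under the half-open sample
#' convention (a run ending at sample `i` ends at `i/rate` seconds).
#'
#' @param stim_channel numeric vector (mV) of the stimulation recording.
#' @param rate sampling rate in Hz.
#' @param threshold detection threshold in mV; default 10x the channel's
#'   global median absolute value.
#' @param nominal_rate,pulse_width carried into the returned log.
#' @return a [stim_pulse_log()]; empty (with a warning) when no pulses are
#'   found.
#' @export
detect_stim_pulses <- function(stim_channel, rate, threshold = NULL,
                               nominal_rate = NA_real_,
                               pulse_width = NA_real_) {
  stopifnot(rate > 0)
  if (is.null(threshold))
    threshold <- 10 * stats::median(abs(stim_channel))
  if (!is.finite(threshold) || threshold <= 0) {
    warning("non-positive pulse threshold; no pulses detected")
    return(stim_pulse_log(numeric(0), nominal_rate, pulse_width))
  }
  above <- abs(stim_channel) >= threshold
  if (!any(above)) {
    warning("no stimulation pulses found")
    return(stim_pulse_log(numeric(0), nominal_rate, pulse_width))
  }
  r <- rle(above)
  # merge gaps of < 2 samples between supra-threshold runs
  inner <- which(!r$values & r$lengths < 2)
  inner <- inner[inner > 1 & inner < length(r$values)]
  if (length(inner)) {
    r$values[inner] <- TRUE
    r <- rle(rep(r$values, r$lengths))
  }
  ends <- cumsum(r$lengths)
  pulse_ends <- ends[r$values]
  stim_pulse_log(pulse_ends / rate, nominal_rate, pulse_width)
}

#' Read / write annotation logs and detected-event tables
#'
#' Annotation logs are delimited text with columns
#' `label` (`step` or `non_functional`), `side`, `onset_s`, `offset_s`.
#' Detected step events use columns `side`, `swing_start_s`, `peak_time_s`,
#' `zero_cross_s`, `stance_end_s`.
#'
#' @param path file path.
#' @return `read_annotations()`: validated data.frame sorted by onset.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "side", "onset_s", "offset_s")
  if (!all(need %in% names(df)))
    stop("annotation log must have columns: ", paste(need, collapse = ", "))
  validate_annotations(df)
}

#' @param annotations data.frame of events.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
validate_annotations <- function(annotations) {
  bad <- which(!(annotations$label %in% c("step", "non_functional")))
  if (length(bad)) stop("unknown annotation label: ", annotations$label[bad[1]])
  if (any(annotations$onset_s >= annotations$offset_s))
    stop("annotation onset_s must be < offset_s")
  annotations[order(annotations$onset_s), , drop = FALSE]
}

#' @param events data.frame of detected step events.
#' @rdname read_annotations
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
read_events <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
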