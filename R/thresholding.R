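#' Find the rest period inside one analysis bin
#'
#' Rest discovery inside a 10 s bin of the activity envelope:
#' \enumerate{
#'   \item block-average the envelope over non-overlapping `avg_window_s`
#'     (10 ms) windows;
#'   \item seed at the block with the minimum mean (earliest block on ties);
#'   \item grow the window left and right, admitting a neighbouring block
#'     while (a) the first-differential magnitude of adjacent block means
#'     stays below the stop criterion and (b) when `use_log`, the running
#'     log-deviation `sum |ln((m[b]+eps)/(m_seed+eps))|` over admitted
#'     blocks stays `<= log_thresh` -- the second criterion stops slow
#'     ramps whose per-block differential never triggers;
#'   \item compute `mu_rest`, `sigma_rest` from the raw envelope samples
#'     inside the grown window.
#' }
#' Growth alternates left/right each round and a side that fails once is
#' closed for good, so the procedure is deterministic.
#'
#' The first-differential stop has two modes. `"relative"` (default)
#' compares `|m[b] - m[b_adjacent]| / avg_window_s / m_seed` against
#' `dmax_rel`: the change per second expressed in multiples of the seed
#' rest level. A genuine burst onset multiplies the envelope several-fold
#' within a block or two (thousands of %/s), while rest-level modulation
#' (noise, stimulation-locked ripple) stays within a fraction of the rest
#' level per block; the default 500/s separates the two and makes rest
#' discovery -- and hence the burst thresholds -- invariant under positive
#' rescaling of the envelope. `"absolute"` compares
#' `|m[b] - m[b_adjacent]| / avg_window_s` against `dmax` in envelope
#' units per second, for data whose absolute scale is calibrated.
#'
#' @param env an [envelope()].
#' @param bin numeric `c(start_s, end_s)` in recording time, half-open; must
#'   lie inside the envelope.
#' @param avg_window_s block-averaging window (default 10 ms).
#' @param dmax absolute first-differential stop (envelope units/s), used
#'   when `dmax_mode = "absolute"`.
#' @param dmax_rel relative first-differential stop (multiples of the seed
#'   rest level per second), used when `dmax_mode = "relative"`.
#' @param dmax_mode `"relative"` (scale-free, default) or `"absolute"`.
#' @param log_thresh log-deviation stop (default 300).
#' @param use_log enable the log-deviation criterion.
#' @return object of class `rest_segment`: list with `bin_start`, `bin_end`,
#'   `start_s`, `end_s`, `mu_rest`, `sigma_rest`, `n_samples`.
#' @export
find_rest_period <- function(env, bin, avg_window_s = 0.01, dmax = 0.1,
                             dmax_rel = 500,
                             dmax_mode = c("relative", "absolute"),
                             log_thresh = 300, use_log = TRUE) {
  dmax_mode <- match.arg(dmax_mode)
  stopifnot(inherits(env, "envelope"), length(bin) == 2, bin[2] > bin[1])
  rate <- env$rate
  n <- length(env$values)
  i0 <- floor((bin[1] - env$t0) * rate + 1e-9) + 1
  i1 <- floor((bin[2] - env$t0) * rate + 1e-9)
  if (i0 < 1 || i1 > n) stop("bin must lie inside the envelope")
  v <- env$values[i0:i1]
  block_len <- max(1L, round(avg_window_s * rate))
  n_blocks <- length(v) %/% block_len
  if (n_blocks < 2) stop("bin shorter than 2 averaging blocks")
  means <- colMeans(matrix(v[seq_len(n_blocks * block_len)],
                           nrow = block_len))
  seed <- which.min(means)
  eps <- 1e-12
  ldev <- abs(log((means + eps) / (means[seed] + eps)))
  lo <- hi <- seed
  cum_log <- 0
  open_l <- TRUE; open_r <- TRUE
  admit <- function(cand, edge) {
    d <- abs(means[cand] - means[edge]) / avg_window_s
    if (dmax_mode == "relative") {
      if (d > 0) {
        d_rel <- if (means[seed] > 0) d / means[seed] else Inf
        if (d_rel > dmax_rel) return(FALSE)
      }
    } else {
      if (d > dmax) return(FALSE)
    }
    if (use_log && cum_log + ldev[cand] > log_thresh) return(FALSE)
    TRUE
  }
  while (open_l || open_r) {
    if (open_l) {
      if (lo > 1 && admit(lo - 1, lo)) {
        lo <- lo - 1
        cum_log <- cum_log + ldev[lo]
      } else open_l <- FALSE
    }
    if (open_r) {
      if (hi < n_blocks && admit(hi + 1, hi)) {
        hi <- hi + 1
        cum_log <- cum_log + ldev[hi]
      } else open_r <- FALSE
    }
  }
  s0 <- (lo - 1) * block_len + 1
  s1 <- hi * block_len
  seg <- v[s0:s1]
  sigma <- if (length(seg) > 1) stats::sd(seg) else 0
  structure(list(
    bin_start = bin[1], bin_end = bin[2],
    start_s = bin[1] + (s0 - 1) / rate,
    end_s = bin[1] + s1 / rate,
    mu_rest = mean(seg), sigma_rest = sigma,
    n_samples = length(seg)
  ), class = "rest_segment")
}

#' Burst magnitude + duration threshold from rest statistics
#'
#' The magnitude criterion is `mu_rest + J * sigma_rest` (scaling constant
#' `J = 7` by default). The duration criterion is per-muscle: a
#' supra-threshold run must last at least 0.1 s on TA (flexor) and 0.3 s on
#' Sol (extensor) to count as a burst.
#'
#' @param rest a `rest_segment` from [find_rest_period()].
#' @param J scaling constant (> 0).
#' @param muscle `"TA"` or `"Sol"`, selects the default duration criterion.
#' @param min_duration_s explicit duration criterion in seconds, overriding
#'   the per-muscle default.
#' @return object of class `burst_threshold`: list with `magnitude`
#'   (envelope units), `min_duration_s`, `mu_rest`, `sigma_rest`.
#' @export
#' @examples
#' r <- structure(list(mu_rest = 0.10, sigma_rest = 0.02),
#'                class = "rest_segment")
#' compute_threshold(r, J = 7, muscle = "TA")$magnitude  # 0.24
compute_threshold <- function(rest, J = 7, muscle = c("TA", "Sol"),
                              min_duration_s = NULL) {
  if (J <= 0) stop("J must be > 0")
  muscle <- match.arg(muscle)
  if (is.null(min_duration_s))
    min_duration_s <- if (muscle == "TA") 0.1 else 0.3
  structure(list(
    magnitude = rest$mu_rest + J * rest$sigma_rest,
    min_duration_s = min_duration_s,
    mu_rest = rest$mu_rest, sigma_rest = rest$sigma_rest
  ), class = "burst_threshold")
}

#' Per-bin burst thresholds across an envelope
#'
#' Splits the envelope span into `bin_s` (10 s) bins, finds the rest period
#' and the resulting magnitude threshold in each. A trailing partial bin is
#' processed when at least `min_partial_bin_s` long, otherwise it inherits
#' the previous bin's statistics.
#'
#' @param env an [envelope()] with a known `muscle` role (or pass `muscle`).
#' @param config configuration list, see [tokeda_config()].
#' @param muscle `"TA"` or `"Sol"`; defaults to the envelope's role.
#' @return data.frame with one row per bin: `bin_index`, `start_s`, `end_s`,
#'   `mu_rest`, `sigma_rest`, `magnitude`, `min_duration_s`.
#' @export
compute_bin_thresholds <- function(env, config = tokeda_config(),
                                   muscle = NULL) {
  tc <- config$thresholding
  if (is.null(muscle)) muscle <- env$muscle
  if (is.na(muscle) || !muscle %in% c("TA", "Sol"))
    stop("envelope has no TA/Sol muscle role; pass `muscle`")
  min_dur <- if (muscle == "TA") tc$min_duration_ta_s else tc$min_duration_sol_s
  dur <- length(env$values) / env$rate
  starts <- seq(0, dur, by = tc$bin_s)
  starts <- starts[starts < dur - 1e-9]
  out <- vector("list", length(starts))
  prev <- NULL
  for (k in seq_along(starts)) {
    b0 <- starts[k]
    b1 <- min(b0 + tc$bin_s, dur)
    if (b1 - b0 < tc$min_partial_bin_s && !is.null(prev)) {
      rest <- prev  # short trailing bin inherits the previous statistics
    } else {
      rest <- find_rest_period(env, env$t0 + c(b0, b1),
                               avg_window_s = tc$avg_window_s,
                               dmax = tc$dmax, dmax_rel = tc$dmax_rel,
                               dmax_mode = tc$dmax_mode,
                               log_thresh = tc$log_thresh,
                               use_log = tc$use_log)
      prev <- rest
    }
    thr <- compute_threshold(rest, J = tc$j, muscle = muscle)
    out[[k]] <- data.frame(
      bin_index = k, start_s = env$t0 + b0, end_s = env$t0 + b1,
      mu_rest = rest$mu_rest, sigma_rest = rest$sigma_rest,
      magnitude = thr$magnitude, min_duration_s = min_dur
    )
  }
  do.call(rbind, out)
}

#' Detect EMG bursts by double thresholding
#'
#' Marks maximal runs of envelope samples at or above the bin-local
#' magnitude threshold, then discards runs shorter than the per-muscle
#' duration criterion. Runs crossing a bin boundary are judged against each
#' bin's own magnitude threshold for its samples and survive as one burst if
#' the union run meets the duration criterion, so a single physiological
#' burst is never split into sub-criterion fragments at a bin edge.
#'
#' @param env an [envelope()].
#' @param thresholds data.frame from [compute_bin_thresholds()] (columns
#'   `start_s`, `end_s`, `magnitude`, `min_duration_s`) covering the
#'   envelope span.
#' @return data.frame of bursts: `start_s`, `end_s`, `duration_s` (half-open
#'   intervals in recording time), plus `side`/`muscle` from the envelope.
#' @export
detect_bursts <- function(env, thresholds) {
  rate <- env$rate
  n <- length(env$values)
  thr <- numeric(n)
  for (k in seq_len(nrow(thresholds))) {
    i0 <- max(1, floor((thresholds$start_s[k] - env$t0) * rate + 1e-9) + 1)
    i1 <- min(n, floor((thresholds$end_s[k] - env$t0) * rate + 1e-9))
    if (i0 <= i1) thr[i0:i1] <- thresholds$magnitude[k]
  }
  above <- env$values >= thr
  if (!any(above)) return(empty_bursts(env))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  i0s <- starts[keep]; i1s <- ends[keep]
  # duration criterion from the bin containing the run start
  min_dur <- vapply(i0s, function(i) {
    t <- env$t0 + (i - 1) / rate
    k <- which(thresholds$start_s - 1e-9 <= t & t < thresholds$end_s + 1e-9)[1]
    if (is.na(k)) thresholds$min_duration_s[1] else thresholds$min_duration_s[k]
  }, numeric(1))
  dur <- (i1s - i0s + 1) / rate
  ok <- dur >= min_dur - 1e-12
  if (!any(ok)) return(empty_bursts(env))
  data.frame(
    side = env$side, muscle = env$muscle,
    start_s = env$t0 + (i0s[ok] - 1) / rate,
    end_s = env$t0 + i1s[ok] / rate,
    duration_s = dur[ok],
    stringsAsFactors = FALSE
  )
}

empty_bursts <- function(env) {
  data.frame(side = character(0), muscle = character(0),
             start_s = numeric(0), end_s = numeric(0),
             duration_s = numeric(0), stringsAsFactors = FALSE)
}

#' Export per-bin thresholds as delimited text
#'
#' @param thresholds data.frame from [compute_bin_thresholds()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_thresholds <- function(thresholds, path) {
  utils::write.csv(thresholds, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
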