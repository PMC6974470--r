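#' Default analysis configuration
#'
#' Returns the nested list of numeric parameters used throughout the pipeline.
#' Every value can be overridden either programmatically (pass a nested list
#' via `...`, merged with [utils::modifyList()]) or from a YAML file read with
#' [read_config()].
#'
#' Sections:
#' \describe{
#'   \item{conditioning}{`bandpass_low` (30 Hz), `bandpass_high` (1000 Hz),
#'     `bandpass_order` (3), `smooth_cutoff` (50 Hz), `smooth_order` (3).}
#'   \item{thresholding}{`bin_s` (10 s analysis bins), `avg_window_s` (10 ms
#'     rest-search block), `dmax_mode` (`"relative"`/`"absolute"`
#'     first-differential stop), `dmax_rel` (500 seed-level multiples/s),
#'     `dmax` (0.1 envelope-units/s, absolute mode),
#'     `log_thresh` (300, log-deviation stop), `use_log`,
#'     `j` (7, threshold scaling constant), `min_duration_ta_s` (0.1),
#'     `min_duration_sol_s` (0.3), `min_partial_bin_s` (2).}
#'   \item{steps}{`follow_window_s` (0.5), `diff_threshold` (0.01),
#'     `sol_burst_min_s` (0.25), `peak_separation_s` (0.2).}
#'   \item{mep}{`epoch_s` (0.025), `er_ms`/`mr_ms`/`lr_ms` window bounds,
#'     `min_separation_ms` (0.6), `min_prominence` (0.2 mV),
#'     `d2_threshold` (1.5e6 mV/s^2), `d2_assumed_rate` (10000 Hz),
#'     `interp` ("cubic" or "linear").}
#'   \item{io}{`segment_s` (600 s processing segments),
#'     `stim_threshold_factor` (10, times the channel median absolute value),
#'     `pulse_gap_tol` (0.2 relative inter-pulse tolerance).}
#'   \item{validation}{`tolerance_s` (0.5 event-matching tolerance).}
#' }
#'
#' @param ... named nested lists overriding individual entries, e.g.
#'   `tokeda_config(thresholding = list(j = 5))`.
#' @return nested named list of parameters.
#' @export
#' @examples
#' cfg <- tokeda_config(steps = list(diff_threshold = 0.02))
#' cfg$steps$diff_threshold
tokeda_config <- function(...) {
  cfg <- list(
    conditioning = list(
      bandpass_low = 30, bandpass_high = 1000, bandpass_order = 3,
      smooth_cutoff = 50, smooth_order = 3
    ),
    thresholding = list(
      bin_s = 10, avg_window_s = 0.01, dmax = 0.1, dmax_rel = 500,
      dmax_mode = "relative",
      log_thresh = 300, use_log = TRUE, j = 7,
      min_duration_ta_s = 0.1, min_duration_sol_s = 0.3,
      min_partial_bin_s = 2
    ),
    steps = list(
      follow_window_s = 0.5, diff_threshold = 0.01,
      sol_burst_min_s = 0.25, peak_separation_s = 0.2
    ),
    mep = list(
      epoch_s = 0.025, er_ms = c(1, 4), mr_ms = c(4, 7), lr_ms = c(7, 25),
      min_separation_ms = 0.6, min_prominence = 0.2,
      d2_threshold = 1.5e6, d2_assumed_rate = 10000, interp = "cubic"
    ),
    io = list(
      segment_s = 600, stim_threshold_factor = 10, pulse_gap_tol = 0.2
    ),
    validation = list(tolerance_s = 0.5)
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("configuration overrides must be named")
    cfg <- utils::modifyList(cfg, dots)
  }
  cfg
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML mirroring the structure of
#' [tokeda_config()]; entries missing from the file keep their defaults.
#'
#' @param path file path.
#' @return `read_config()`: the merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(tokeda_config())
  do.call(tokeda_config, user)
}

#' @param cfg configuration list as returned by [tokeda_config()].
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
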