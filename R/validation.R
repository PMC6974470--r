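#' Match detected step events against an annotation log
#'
#' Greedy chronological matching for one limb: detections are visited in
#' time order and each is paired with the earliest unmatched annotated step
#' whose `[onset, offset)` interval overlaps the detected
#' `[swing_start, stance_end)` interval, or whose onset lies within
#' `tolerance_s` of the detected flexion-to-extension crossing. Each
#' annotated event is matched at most once.
#'
#' Counts: `tp` = matched detections, `fp` = unmatched detections,
#' `fn` = unmatched annotated steps, `tn` = annotated non-functional events
#' with no detection overlapping them.
#'
#' @param detected step-event data.frame from [detect_steps()].
#' @param annotations annotation data.frame (`label`, `side`, `onset_s`,
#'   `offset_s`), see [read_annotations()].
#' @param tolerance_s onset-matching tolerance in seconds (> 0); default
#'   0.5, the detector's follow window.
#' @param side optional side filter applied to both tables.
#' @return object of class `match_result`: list with counts `tp`, `fp`,
#'   `fn`, `tn`, data.frame `pairs` (`detected_peak_s`,
#'   `annotated_onset_s`) and `tolerance_s`.
#' @export
match_events <- function(detected, annotations, tolerance_s = 0.5,
                         side = NULL) {
  stopifnot(tolerance_s > 0)
  if (!is.null(side)) {
    detected <- detected[detected$side == side, , drop = FALSE]
    annotations <- annotations[annotations$side == side, , drop = FALSE]
  }
  ann <- annotations[order(annotations$onset_s), , drop = FALSE]
  steps <- ann[ann$label == "step", , drop = FALSE]
  nonf <- ann[ann$label == "non_functional", , drop = FALSE]
  det <- detected[order(detected$peak_time_s), , drop = FALSE]
  matched_ann <- rep(FALSE, nrow(steps))
  matched_det <- rep(FALSE, nrow(det))
  pairs <- list()
  for (i in seq_len(nrow(det))) {
    d0 <- det$swing_start_s[i]; d1 <- det$stance_end_s[i]
    zc <- det$zero_cross_s[i]
    cand <- which(!matched_ann &
                    ((steps$onset_s < d1 & steps$offset_s > d0) |
                       abs(zc - steps$onset_s) <= tolerance_s))
    if (length(cand)) {
      j <- cand[1]  # earliest annotated event in time
      matched_ann[j] <- TRUE
      matched_det[i] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(
        detected_peak_s = det$peak_time_s[i],
        annotated_onset_s = steps$onset_s[j]
      )
    }
  }
  tn <- 0L
  for (k in seq_len(nrow(nonf))) {
    hit <- any(det$swing_start_s < nonf$offset_s[k] &
                 det$stance_end_s > nonf$onset_s[k])
    if (!hit) tn <- tn + 1L
  }
  structure(list(
    tp = sum(matched_det), fp = sum(!matched_det),
    fn = sum(!matched_ann), tn = tn,
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(detected_peak_s = numeric(0), annotated_onset_s = numeric(0)),
    tolerance_s = tolerance_s
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp=%d fp=%d fn=%d tn=%d (tolerance %g s)\n",
              x$tp, x$fp, x$fn, x$tn, x$tolerance_s))
  invisible(x)
}

#' Accuracy, precision and recall of a match result
#'
#' `accuracy = (tp + tn) / total_sampled` (correctly classified events over
#' all sampled events), `precision = tp / (tp + fp)`,
#' `recall = tp / (tp + fn)`. Ratios with a zero denominator are reported
#' as `NA` (missing), never silently as 0 or 1.
#'
#' @param m a `match_result` from [match_events()], or a list with fields
#'   `tp`, `fp`, `fn`, `tn`.
#' @param total_sampled total number of sampled events; defaults to
#'   `tp + fp + fn + tn` and must be at least `tp + fn`.
#' @return list with `accuracy`, `precision`, `recall`.
#' @export
#' @examples
#' score_events(list(tp = 8, fp = 2, fn = 1, tn = 1), total_sampled = 10)
score_events <- function(m, total_sampled = NULL) {
  counts <- c(m$tp, m$fp, m$fn, m$tn)
  if (any(counts < 0)) stop("negative counts")
  if (is.null(total_sampled)) total_sampled <- m$tp + m$fp + m$fn + m$tn
  if (total_sampled < m$tp + m$fn)
    stop("total_sampled must be at least tp + fn")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(
    accuracy = safe(m$tp + m$tn, total_sampled),
    precision = safe(m$tp, m$tp + m$fp),
    recall = safe(m$tp, m$tp + m$fn)
  )
}
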