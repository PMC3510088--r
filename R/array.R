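# Microarray quantification: spot summarization, Rluc normalization, fold
# induction.

#' Summarize spot-level fluorescence per capture and hybridization unit
#'
#' Computes the mean background-corrected signal (signal - background) over
#' spot replicates for each capture within each hybridization unit (a
#' slide/subarray incubated with one labelled sample). Channels mapped to
#' the same sample are pooled as technical replicates. Non-positive
#' corrected means are floored to `epsilon` and flagged `below_floor` so
#' the subsequent log2 transform is defined.
#'
#' @param spots data.frame with columns `slide_id`, `subarray`,
#'   `capture_id`, `spot_replicate`, `channel`, `signal`, `background`.
#' @param samples sample sheet mapping `slide_id`, `subarray`, `channel` to
#'   `sample_id` and `condition`.
#' @param layout optional layout data.frame with a `capture_id` column;
#'   spots whose capture is absent from the layout are an input error.
#' @param epsilon floor for non-positive corrected values, fluorescence
#'   units.
#' @param summary_fun `mean` (default) or `median` spot summarization.
#' @return data.frame with one row per (sample, unit, capture): `sample_id`,
#'   `condition`, `unit`, `capture_id`, `value`, `below_floor`.
#' @export
summarize_spots <- function(spots, samples, layout = NULL, epsilon = 1.0,
                            summary_fun = mean) {
  req <- c("slide_id", "subarray", "capture_id", "spot_replicate",
           "channel", "signal", "background")
  stopifnot(is.data.frame(spots), all(req %in% names(spots)))
  stopifnot(all(c("slide_id", "subarray", "channel", "sample_id",
                  "condition") %in% names(samples)))
  if (any(spots$signal < 0, na.rm = TRUE) ||
      any(spots$background < 0, na.rm = TRUE))
    stop("signal and background must be non-negative", call. = FALSE)
  if (!is.null(layout)) {
    missing <- setdiff(unique(spots$capture_id), unique(layout$capture_id))
    if (length(missing))
      stop("capture(s) absent from layout: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  skey <- paste(spots$slide_id, spots$subarray, spots$channel, sep = "\r")
  mkey <- paste(samples$slide_id, samples$subarray, samples$channel, sep = "\r")
  idx <- match(skey, mkey)
  if (anyNA(idx))
    stop("spot(s) with no sample-sheet entry", call. = FALSE)
  d <- data.frame(sample_id = samples$sample_id[idx],
                  condition = samples$condition[idx],
                  unit = paste(spots$slide_id, spots$subarray, sep = ":"),
                  capture_id = spots$capture_id,
                  corrected = spots$signal - spots$background,
                  stringsAsFactors = FALSE)
  agg <- stats::aggregate(corrected ~ sample_id + condition + unit + capture_id,
                          data = d, FUN = summary_fun)
  names(agg)[names(agg) == "corrected"] <- "value"
  agg$below_floor <- agg$value <= 0
  agg$value[agg$below_floor] <- epsilon
  agg[order(agg$sample_id, agg$unit, agg$capture_id), , drop = FALSE]
}

#' Normalize summarized array values to the Rluc control
#'
#' Divides every UR capture's summarized value by the Rluc value of the
#' same hybridization unit, absorbing transfection-efficiency and labelling
#' differences. A missing or non-positive Rluc value is a hard error.
#'
#' @param values output of [summarize_spots()].
#' @return data.frame with `value` (capture/Rluc ratio) and `log2_value`.
#' @export
normalize_array <- function(values) {
  stopifnot(all(c("sample_id", "unit", "capture_id", "value") %in% names(values)))
  rl <- values[values$capture_id == "Rluc", , drop = FALSE]
  ur <- values[values$capture_id != "Rluc", , drop = FALSE]
  rv <- rl$value[match(ur$unit, rl$unit)]
  if (anyNA(rv))
    stop("missing Rluc value for at least one hybridization unit", call. = FALSE)
  if (any(rv <= 0))
    stop("non-positive Rluc value: normalization impossible", call. = FALSE)
  out <- ur[, intersect(c("sample_id", "condition", "unit", "capture_id",
                          "below_floor"), names(ur)), drop = FALSE]
  out$value <- ur$value / rv
  out$log2_value <- log2(out$value)
  rownames(out) <- NULL
  out
}

#' Per-capture log2 fold induction from normalized array values
#'
#' log2(mean treated normalized value / mean control normalized value) per
#' capture, with a standard error over biological replicates combined from
#' the per-condition SEMs of sample-level log2 values. Hybridization units
#' of the same sample are averaged first (technical replicates).
#'
#' @param values data.frame from [normalize_array()].
#' @param treated,control condition labels.
#' @return data.frame with `target`, `log2_fi`, `sem`, `n_treated`,
#'   `n_control`.
#' @export
array_fold_induction <- function(values, treated = "treated",
                                 control = "control") {
  stopifnot(all(c("sample_id", "condition", "capture_id", "value") %in%
                  names(values)))
  per_sample <- stats::aggregate(value ~ sample_id + condition + capture_id,
                                 data = values, FUN = mean)
  per_sample$log2_value <- log2(per_sample$value)
  per_sample$target <- per_sample$capture_id
  fold_induction(per_sample, treated = treated, control = control)
}
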