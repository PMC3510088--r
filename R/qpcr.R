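# qPCR absolute quantification: standard curves, copy numbers, Rluc
# normalization, fold induction.

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(copies) over a dilution series. The
#' amplification efficiency per cycle is E = 10^(-1/slope); a slope of
#' -3.3219 corresponds to perfect doubling (E = 2).
#'
#' @param points data.frame with columns `copies` (> 0) and `ct`.
#' @return object of class `ur_standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency` and the fitted `ct_range`.
#' @export
#' @examples
#' pts <- data.frame(copies = 10^(2:7), ct = 40 - 3.3219 * (2:7))
#' fit_standard_curve(pts)$efficiency
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points), all(c("copies", "ct") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("copies", "ct")]), ]
  if (nrow(points) < 3)
    stop("standard curve needs at least 3 dilution points", call. = FALSE)
  if (any(points$copies <= 0))
    stop("copies must be positive", call. = FALSE)
  lx <- log10(points$copies)
  if (max(lx) - min(lx) < .Machine$double.eps^0.5)
    stop("dilution series has zero variance in copies", call. = FALSE)
  fit <- stats::lm(ct ~ lx, data = data.frame(ct = points$ct, lx = lx))
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((points$ct - mean(points$ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  curve <- list(slope = slope,
                intercept = unname(stats::coef(fit)[1]),
                r_squared = r2,
                efficiency = 10^(-1 / slope),
                ct_range = range(points$ct),
                copies_range = range(points$copies))
  class(curve) <- "ur_standard_curve"
  curve
}

#' @export
print.ur_standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: Ct = %.4f log10(copies) + %.4f, E = %.3f, R2 = %.4f\n",
              x$slope, x$intercept, x$efficiency, x$r_squared))
  invisible(x)
}

#' Gate a standard curve on amplification efficiency
#'
#' Accepts curves whose efficiency lies inside the inclusive window,
#' by default E in \[1.6, 2.4\]. Out-of-window curves are flagged with a
#' warning naming the target; they are reported, not silently dropped.
#'
#' @param curve an [fit_standard_curve()] object.
#' @param e_min,e_max inclusive efficiency bounds.
#' @param target optional target name for the warning message.
#' @return logical scalar.
#' @export
gate_efficiency <- function(curve, e_min = 1.6, e_max = 2.4, target = NULL) {
  ok <- curve$efficiency >= e_min && curve$efficiency <= e_max
  if (!ok)
    warning(sprintf("amplification efficiency %.3f outside [%.2f, %.2f]%s",
                    curve$efficiency, e_min, e_max,
                    if (is.null(target)) "" else paste0(" for target ", target)),
            call. = FALSE)
  ok
}

#' Convert Ct values to absolute copy numbers
#'
#' Inverts the standard curve: copies = 10^((ct - intercept)/slope).
#' Not-detected wells (NA Ct) propagate as NA, never as zero. Values whose
#' Ct lies outside the fitted dilution range are returned with an
#' `extrapolated` attribute flagging them.
#'
#' @param ct numeric vector of Ct values (NA = not detected).
#' @param curve an [fit_standard_curve()] object.
#' @return numeric vector of copy numbers with logical attribute
#'   `extrapolated`.
#' @export
ct_to_copies <- function(ct, curve) {
  copies <- 10^((ct - curve$intercept) / curve$slope)
  extra <- !is.na(ct) & (ct < curve$ct_range[1] | ct > curve$ct_range[2])
  attr(copies, "extrapolated") <- extra
  copies
}

#' Normalize UR copy numbers to the Rluc co-transfection control
#'
#' Converts every Ct record to copies with its target's standard curve and
#' divides each UR measurement by the Rluc measurement of the same sample
#' and replicate, cancelling per-sample transfection-efficiency and global
#' expression differences. Missing or zero Rluc is a hard error:
#' normalization is then impossible.
#'
#' @param records data.frame with columns `sample_id`, `condition`,
#'   `target`, `replicate`, `ct`, and optionally `experiment`.
#' @param curves named list of standard curves (one per target, `Rluc`
#'   included), or a single curve shared by all targets.
#' @return data.frame with `value` (UR/Rluc copy ratio) and `log2_value`.
#' @export
normalize_to_rluc <- function(records, curves) {
  req <- c("sample_id", "condition", "target", "replicate", "ct")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  shared <- inherits(curves, "ur_standard_curve")
  curve_for <- function(target) {
    if (shared) return(curves)
    cv <- curves[[target]]
    if (is.null(cv)) stop("no standard curve for target ", target, call. = FALSE)
    cv
  }
  records$copies <- vapply(seq_len(nrow(records)), function(i) {
    as.numeric(ct_to_copies(records$ct[i], curve_for(records$target[i])))
  }, numeric(1))

  ur <- records[records$target != "Rluc", , drop = FALSE]
  rl <- records[records$target == "Rluc", , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$replicate, sep = "\r")
  rl_copies <- rl$copies[match(key(ur), key(rl))]
  if (anyNA(rl_copies) && any(is.na(rl_copies) & !is.na(ur$copies)))
    stop("missing Rluc record for at least one sample/replicate", call. = FALSE)
  if (any(!is.na(rl_copies) & rl_copies == 0))
    stop("Rluc copy number of zero: normalization impossible", call. = FALSE)
  out <- ur[, intersect(c("sample_id", "condition", "target", "replicate",
                          "experiment"), names(ur)), drop = FALSE]
  out$value <- ur$copies / rl_copies
  out$log2_value <- log2(out$value)
  rownames(out) <- NULL
  out
}

#' Per-target log2 fold induction from normalized expression
#'
#' For every target present in both conditions, computes
#' log2(mean treated value / mean control value), a standard error over
#' biological replicates (combined from the per-condition SEMs of the
#' replicate-level log2 values), and the replicate counts. Not-detected
#' replicates (NA) are excluded from the means.
#'
#' @param expr data.frame from [normalize_to_rluc()] (columns `condition`,
#'   `target`, `value`, `log2_value`).
#' @param treated,control condition labels.
#' @return data.frame with `target`, `log2_fi`, `sem`, `n_treated`,
#'   `n_control`.
#' @export
fold_induction <- function(expr, treated = "treated", control = "control") {
  stopifnot(all(c("condition", "target", "value", "log2_value") %in% names(expr)))
  targets <- unique(expr$target)
  rows <- lapply(targets, function(tg) {
    tv <- expr$value[expr$target == tg & expr$condition == treated]
    cv <- expr$value[expr$target == tg & expr$condition == control]
    tl <- expr$log2_value[expr$target == tg & expr$condition == treated]
    cl <- expr$log2_value[expr$target == tg & expr$condition == control]
    tv <- tv[!is.na(tv)]; cv <- cv[!is.na(cv)]
    tl <- tl[!is.na(tl)]; cl <- cl[!is.na(cl)]
    if (!length(tv) || !length(cv))
      stop("both conditions required for target ", tg, call. = FALSE)
    if (mean(cv) <= 0) stop("control mean <= 0 for target ", tg, call. = FALSE)
    sem_sq <- function(x) if (length(x) > 1) stats::var(x) / length(x) else 0
    data.frame(target = tg,
               log2_fi = log2(mean(tv) / mean(cv)),
               sem = sqrt(sem_sq(tl) + sem_sq(cl)),
               n_treated = length(tv),
               n_control = length(cv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
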