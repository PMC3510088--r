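# Result reporting.

#' Tabulate posterior summaries for reporting
#'
#' One row per (treatment, target) with the posterior mean log2 fold
#' induction, 95% credible interval, tail p-value, significance call and
#' failed-rule reasons, sorted by decreasing |posterior mean| within each
#' treatment. An empty input yields a header-only table with the stable
#' column order.
#'
#' @param results data.frame from [call_significance()] (possibly several
#'   treatments row-bound), or NULL/empty.
#' @return data.frame with stable columns `treatment`, `target`,
#'   `posterior_mean`, `ci_low`, `ci_high`, `p_value`, `significant`,
#'   `reasons`.
#' @export
report_table <- function(results) {
  cols <- c("treatment", "target", "posterior_mean", "ci_low", "ci_high",
            "p_value", "significant", "reasons")
  if (is.null(results) || !nrow(results)) {
    empty <- data.frame(treatment = character(0), target = character(0),
                        posterior_mean = numeric(0), ci_low = numeric(0),
                        ci_high = numeric(0), p_value = numeric(0),
                        significant = logical(0), reasons = character(0),
                        stringsAsFactors = FALSE)
    return(empty)
  }
  stopifnot(all(cols %in% names(results)))
  out <- results[order(results$treatment, -abs(results$posterior_mean)),
                 cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the summary TSV and per-treatment text reports
#'
#' @param results data.frame from [call_significance()].
#' @param dir output directory (created if absent).
#' @return invisibly, the summary TSV path.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report_table(results)
  path <- file.path(dir, "posterior_summary.tsv")
  write_table(tab, path)
  for (tr in unique(tab$treatment)) {
    sub <- tab[tab$treatment == tr, , drop = FALSE]
    lines <- c(sprintf("Treatment: %s", tr),
               sprintf("Significant reporters: %d of %d",
                       sum(sub$significant), nrow(sub)), "")
    lines <- c(lines, vapply(seq_len(nrow(sub)), function(i) {
      sprintf("%-20s log2 FI %6.2f  95%% CrI [%6.2f, %6.2f]  p %.1e  %s%s",
              sub$target[i], sub$posterior_mean[i], sub$ci_low[i],
              sub$ci_high[i], sub$p_value[i],
              if (sub$significant[i]) "SIGNIFICANT" else "ns",
              if (nzchar(sub$reasons[i])) paste0(" (", sub$reasons[i], ")")
              else "")
    }, character(1)))
    writeLines(lines, file.path(dir, paste0("report_", gsub("[^A-Za-z0-9]+",
                                                            "_", tr), ".txt")))
  }
  invisible(path)
}
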