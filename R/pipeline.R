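# Umbrella pipelines chaining quantification and inference.

#' Run the qPCR analysis pipeline
#'
#' Fits a standard curve per target from the dilution series, gates each
#' on amplification efficiency (flagging, not dropping, out-of-window
#' targets), converts Ct values to absolute copies, normalizes to Rluc,
#' fits the three-way Bayesian ANOVA on the log2 normalized copy numbers
#' and returns significance-called posterior summaries.
#'
#' @param plate Ct records (see [read_plate()]); an `experiment` column
#'   identifies the repeated-experiment factor (defaults to a single
#'   experiment when absent).
#' @param standards dilution series (see [read_standards()]).
#' @param spec an [model_spec()] for platform `"qpcr"`.
#' @param treatment treatment label recorded in the output.
#' @param e_min,e_max efficiency gate bounds.
#' @param alpha,basal_band significance-rule parameters.
#' @return list with `summary` (significance-called posterior table),
#'   `expression` (normalized values), `curves`, `efficiency_ok` and the
#'   underlying `fit`.
#' @export
run_qpcr_pipeline <- function(plate, standards, spec = model_spec("qpcr"),
                              treatment = "treated",
                              e_min = 1.6, e_max = 2.4,
                              alpha = 0.05, basal_band = c(-1, 1)) {
  stopifnot(spec$platform == "qpcr")
  if (!"experiment" %in% names(plate)) plate$experiment <- 1L
  curves <- lapply(split(standards, standards$target), fit_standard_curve)
  eff_ok <- vapply(names(curves), function(tg)
    suppressWarnings(gate_efficiency(curves[[tg]], e_min, e_max, target = tg)),
    logical(1))
  for (tg in names(eff_ok)[!eff_ok])
    warning(sprintf("target %s: amplification efficiency %.3f outside [%.2f, %.2f]",
                    tg, curves[[tg]]$efficiency, e_min, e_max), call. = FALSE)
  expr <- normalize_to_rluc(plate, curves)
  fit <- fit_bayes_anova(expr, spec)
  summ <- summarize_posterior(fit, treatment = treatment)
  summ <- call_significance(summ, basal_band = basal_band, alpha = alpha)
  summ$treatment <- treatment
  list(summary = summ, expression = expr, curves = curves,
       efficiency_ok = eff_ok, fit = fit)
}

#' Run the microarray analysis pipeline
#'
#' Summarizes spot-level fluorescence, normalizes to Rluc per
#' hybridization unit, fits the two-way repeated-measures Bayesian ANOVA
#' on log2 normalized values and returns significance-called posterior
#' summaries.
#'
#' @param spots,samples,layout microarray inputs (see [read_spots()]).
#' @param spec an [model_spec()] for platform `"microarray"`.
#' @param treatment treatment label recorded in the output.
#' @param alpha,basal_band significance-rule parameters.
#' @param epsilon floor for non-positive background-corrected values.
#' @return list with `summary`, `values` (normalized) and the `fit`.
#' @export
run_array_pipeline <- function(spots, samples, layout = NULL,
                               spec = model_spec("microarray"),
                               treatment = "treated",
                               alpha = 0.05, basal_band = c(-1, 1),
                               epsilon = 1.0) {
  stopifnot(spec$platform == "microarray")
  summarized <- summarize_spots(spots, samples, layout, epsilon = epsilon)
  values <- normalize_array(summarized)
  dat <- values
  dat$target <- dat$capture_id
  fit <- fit_bayes_anova(dat, spec)
  summ <- summarize_posterior(fit, treatment = treatment)
  summ <- call_significance(summ, basal_band = basal_band, alpha = alpha)
  summ$treatment <- treatment
  list(summary = summ, values = values, fit = fit)
}

#' Simulate a published-treatment scenario and recover fold inductions
#'
#' End-to-end wrapper: builds the treatment's library-wide synthetic
#' design via [scenario_from_table1()], simulates a qPCR experiment,
#' and runs the full quantification + inference pipeline.
#'
#' @param treatment_label treatment in [table1_effects()].
#' @param seed simulation seed (also seeds the sampler).
#' @param spec model spec; default uses 2 chains x 1500 iterations after
#'   500 burn-in, adequate for this conjugate-like ANOVA.
#' @param ... passed to [scenario_from_table1()] (noise levels, replicate
#'   structure).
#' @return the [run_qpcr_pipeline()] result list, with the design's true
#'   effects attached as `true_log2_fi`.
#' @export
run_scenario <- function(treatment_label, seed = 1L,
                         spec = model_spec("qpcr", chains = 2L,
                                           iterations = 1500L,
                                           burn_in = 500L, adapt = 500L,
                                           seed = seed),
                         ...) {
  design <- scenario_from_table1(treatment_label, seed = seed, ...)
  sim <- simulate_qpcr(design)
  res <- run_qpcr_pipeline(sim$plate, sim$standards, spec = spec,
                           treatment = treatment_label)
  res$true_log2_fi <- design$true_log2_fi
  res
}
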