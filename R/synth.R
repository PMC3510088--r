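# Synthetic qPCR plates, dilution series and microarray spot tables with
# known ground truth.

# Published per-treatment posterior summaries for the qPCR platform
# (log2 fold induction, 1 SEM each way, posterior tail p-value); used to
# parameterize recovery scenarios.
TABLE1_EFFECTS <- data.frame(
  treatment = c(rep("Dexamethasone", 3), rep("TPA", 5), rep("Forskolin", 3),
                rep("8-bromo-cAMP", 2), rep("IBMX", 2), rep("EHNA", 2),
                rep("Rolipram", 2), rep("8-bromo-cGMP", 2),
                rep("Vardenafil citrate", 2), rep("Sildenafil citrate", 2)),
  target = c("GRE", "GRE(PRE/ARE/MRE)", "SRE/SRF",
             "NF-kB", "c-Rel;RelA", "NF-kB(2)", "c-Jun", "AP1/TRE",
             "CREB", "ATF/1/2/3", "SRE/SRF",
             "CREB", "ATF", "CREB", "ATF", "CREB", "ATF", "CREB", "ATF",
             "CREB", "ATF", "CREB", "ATF", "CREB", "ATF"),
  log2_fi = c(3.8, 2.9, 2.0,
              4.4, 3.9, 3.2, 3.2, 2.3,
              13.6, 12.8, 3.3,
              4.5, 3.4, 4.6, 4.1, 4.1, 3.6, 4.4, 3.6,
              0.3, 0.2, 0.3, 0.7, 0.5, -0.3),
  sem = c(0.6, 0.4, 0.3,
          0.6, 0.4, 0.2, 0.7, 0.4,
          0.5, 0.1, 0.2,
          0.2, 0.4, 0.1, 0.0, 0.3, 0.2, 0.3, 0.2,
          0.2, 0.2, 0.2, 0.2, 0.2, 0.2),
  p_value = c(1.0e-9, 1.0e-9, 1.0e-9,
              1.0e-9, 1.0e-9, 1.0e-9, 1.0e-9, 2.2e-5,
              1.0e-9, 1.0e-9, 1.0e-9,
              1.0e-9, 1.0e-9, 1.0e-9, 1.0e-9, 2.2e-5, 2.5e-3,
              1.0e-9, 1.0e-9,
              5.1e-1, 4.0e-1, 2.5e-1, 5.2e-1, 4.1e-1, 5.5e-1),
  stringsAsFactors = FALSE
)

# Cadmium activates the metal-responsive and antioxidant-response
# reporters; the published per-reporter magnitudes live in supplementary
# material not redistributed here, so these are synthetic stand-in effect
# sizes consistent with strong MRE and clear ARE induction.
CADMIUM_EFFECTS <- data.frame(
  treatment = "Cadmium",
  target = c("MRE", "ARE"),
  log2_fi = c(4.5, 3.0),
  sem = c(0.4, 0.3),
  p_value = c(1.0e-9, 1.0e-9),
  stringsAsFactors = FALSE
)

#' Published qPCR effect-size table
#'
#' Per-treatment posterior mean log2 fold inductions (with 1 SEM each way
#' and posterior tail p-values) for the reporters responding to each
#' inducer on the qPCR platform, plus the synthetic stand-in cadmium
#' magnitudes used by the cadmium scenario.
#' @return data.frame with `treatment`, `target`, `log2_fi`, `sem`,
#'   `p_value`.
#' @export
table1_effects <- function() {
  rbind(TABLE1_EFFECTS, CADMIUM_EFFECTS)
}

# A representative 60-reporter library: all reporters named in the
# effect-size tables plus common TFBS reporters, padded to 60.
default_library_targets <- function(n = 60L) {
  named <- unique(c(TABLE1_EFFECTS$target, CADMIUM_EFFECTS$target))
  extras <- c("AP2", "SP1", "p53", "STAT1", "STAT3", "E2F1", "MYC",
              "HIF1A", "NFAT", "OCT1", "GATA1", "GATA3", "ETS1", "ELK1",
              "EGR1", "HSE/HSF1", "XRE/AHR", "PPRE/PPARG", "RARE/RAR",
              "VDRE/VDR", "ERE/ESR1", "ISRE/IRF1", "GAS/STAT5", "SMAD3/4",
              "TCF/LEF", "FOXO1", "FOXO3", "MEF2", "NRF1", "YY1", "CEBPB",
              "USF1", "SREBP1", "CHOP", "PAX6", "SOX2", "NANOG", "KLF4",
              "RUNX1", "MITF", "TFEB", "ATF4", "ATF6", "XBP1", "HNF4A",
              "NRF2/ARE2", "TEAD1", "SRF2", "IRF3", "REST", "SNAI1",
              "TWIST1", "ZEB1", "GLI1", "NOTCH/RBPJ")
  out <- c(named, extras)
  if (length(out) < n) stop("not enough library target names", call. = FALSE)
  out[seq_len(n)]
}

#' Define a synthetic experiment with known ground truth
#'
#' Encodes the generative model both platform simulators draw from: a
#' per-sample transfection scale shared by every target including Rluc,
#' per-target basal copy numbers, treatment effects as true log2 fold
#' inductions applied to treated samples, multiplicative lognormal
#' replicate noise (default coefficient of variation 0.30, the observed
#' ceiling of intra-experimental replicate variation), and a per-
#' experiment Normal jitter of the realized log2 fold change whose ~2 sd
#' excursion equals the observed ceiling of inter-experimental
#' fold-change variation (default 0.60, i.e. jitter sd log2(1.6)/2).
#'
#' @param targets character vector of reporter names (without `Rluc`).
#' @param treatment treatment label.
#' @param true_log2_fi named numeric vector of true log2 fold inductions;
#'   targets not named get 0.
#' @param n_biological_replicates biological replicates per condition per
#'   experiment.
#' @param n_experiments independent experiment repeats (the third qPCR
#'   ANOVA factor).
#' @param replicate_cv lognormal coefficient of variation of replicate-
#'   level copy-number noise.
#' @param inter_experiment_cv ceiling (as a fraction) of per-experiment
#'   fold-change variation; the treated-sample log2 jitter sd is
#'   `log2(1 + inter_experiment_cv)/2`.
#' @param transfection_scale_sd standard deviation (natural-log scale) of
#'   the per-sample transfection efficiency shared between URs and Rluc.
#' @param base_copies named numeric vector of basal transcript copies; a
#'   single unnamed value is recycled for all URs; `Rluc` defaults to 1e5.
#' @param curve_slope,curve_intercept standard-curve parameters mapping
#'   log10(copies) to Ct for every target.
#' @param array_gain fluorescence units per transcript copy.
#' @param background_level additive spot background, fluorescence units.
#' @param spot_cv coefficient of variation of spot-level fluorescence
#'   noise.
#' @param seed integer seed.
#' @return object of class `ur_synthetic_design`.
#' @export
synthetic_design <- function(targets,
                             treatment = "treatment",
                             true_log2_fi = numeric(0),
                             n_biological_replicates = 4L,
                             n_experiments = 3L,
                             replicate_cv = 0.30,
                             inter_experiment_cv = 0.60,
                             transfection_scale_sd = 0.30,
                             base_copies = 1e4,
                             curve_slope = -1 / log10(2),
                             curve_intercept = 37,
                             array_gain = 0.1,
                             background_level = 200,
                             spot_cv = 0.10,
                             seed = 1L) {
  stopifnot(length(targets) >= 1, !"Rluc" %in% targets)
  if (any(duplicated(targets))) stop("duplicate targets", call. = FALSE)
  fi <- stats::setNames(rep(0, length(targets)), targets)
  if (length(true_log2_fi)) {
    unknown <- setdiff(names(true_log2_fi), targets)
    if (length(unknown))
      stop("effects for unknown target(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    fi[names(true_log2_fi)] <- true_log2_fi
  }
  if (replicate_cv < 0 || inter_experiment_cv < 0 || transfection_scale_sd < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  bc <- stats::setNames(rep(1e4, length(targets) + 1L), c(targets, "Rluc"))
  bc["Rluc"] <- 1e5
  if (is.null(names(base_copies))) {
    bc[targets] <- base_copies[1]
  } else {
    unknown <- setdiff(names(base_copies), names(bc))
    if (length(unknown))
      stop("base copies for unknown target(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    bc[names(base_copies)] <- base_copies
  }
  if (any(bc <= 0)) stop("base copies must be positive", call. = FALSE)
  d <- list(targets = targets, treatment = treatment, true_log2_fi = fi,
            n_biological_replicates = as.integer(n_biological_replicates),
            n_experiments = as.integer(n_experiments),
            replicate_cv = replicate_cv,
            inter_experiment_cv = inter_experiment_cv,
            transfection_scale_sd = transfection_scale_sd,
            base_copies = bc,
            curve_slope = curve_slope, curve_intercept = curve_intercept,
            array_gain = array_gain, background_level = background_level,
            spot_cv = spot_cv, seed = as.integer(seed))
  class(d) <- "ur_synthetic_design"
  d
}

#' @export
print.ur_synthetic_design <- function(x, ...) {
  cat(sprintf(paste0("Synthetic design '%s': %d targets, %d experiments x %d ",
                     "replicates,\n  replicate cv %.2f, inter-experiment cv ",
                     "%.2f, transfection sdlog %.2f, seed %d\n"),
              x$treatment, length(x$targets), x$n_experiments,
              x$n_biological_replicates, x$replicate_cv,
              x$inter_experiment_cv, x$transfection_scale_sd, x$seed))
  invisible(x)
}

# lognormal multiplier with unit mean and given coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# True copy numbers per (experiment, condition, replicate, target),
# shared generative core of both platform simulators.
simulate_copies <- function(design) {
  targets <- design$targets
  grid <- expand.grid(experiment = seq_len(design$n_experiments),
                      condition = c("control", "treated"),
                      replicate = seq_len(design$n_biological_replicates),
                      stringsAsFactors = FALSE)
  # Per-experiment, per-target jitter of the realized log2 fold change.
  # "Varied up to X%" is a ceiling on the excursion of fold-change values,
  # so the jitter sd is set to make a ~2 sd excursion multiply the fold
  # change by (1 + cv): sd = log2(1 + cv)/2.
  sd_ie <- log2(1 + design$inter_experiment_cv) / 2
  fi_jitter <- matrix(stats::rnorm(design$n_experiments * length(targets),
                                   0, sd_ie),
                      nrow = design$n_experiments,
                      dimnames = list(NULL, targets))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e <- grid$experiment[i]; cond <- grid$condition[i]; r <- grid$replicate[i]
    s <- if (design$transfection_scale_sd > 0)
      stats::rlnorm(1, 0, design$transfection_scale_sd) else 1
    fi <- if (cond == "treated")
      design$true_log2_fi + fi_jitter[e, ] else
      stats::setNames(rep(0, length(targets)), targets)
    copies_ur <- design$base_copies[targets] * s * 2^fi *
      rlnorm_cv(length(targets), design$replicate_cv)
    copies_rl <- design$base_copies[["Rluc"]] * s *
      rlnorm_cv(1, design$replicate_cv)
    data.frame(sample_id = sprintf("E%d_%s_R%d", e, cond, r),
               experiment = e, condition = cond, replicate = r,
               target = c(targets, "Rluc"),
               copies = c(copies_ur, copies_rl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a qPCR plate and dilution series from a synthetic design
#'
#' Draws true copy numbers from the design's generative model (shared
#' transfection scale per sample including Rluc, treatment effects on
#' treated samples, lognormal replicate noise, per-experiment fold-change
#' jitter) and maps them to Ct values through the design's standard curve.
#' A noise-free 10-fold dilution series per target is emitted alongside so
#' the quantification stage can refit the curves.
#'
#' @param design an [synthetic_design()] object.
#' @param dilution_copies copies of the dilution points.
#' @param dilution_jitter_sd optional Gaussian Ct jitter on the series.
#' @return list with `plate` (Ct records) and `standards` (dilution
#'   series) data.frames, plus the `design`.
#' @export
simulate_qpcr <- function(design, dilution_copies = 10^(2:7),
                          dilution_jitter_sd = 0) {
  stopifnot(inherits(design, "ur_synthetic_design"))
  with_preserved_rng(design$seed, {
    copies <- simulate_copies(design)
    plate <- copies[, c("sample_id", "experiment", "condition", "replicate",
                        "target")]
    plate$ct <- design$curve_intercept +
      design$curve_slope * log10(copies$copies)
    all_targets <- c(design$targets, "Rluc")
    standards <- do.call(rbind, lapply(all_targets, function(tg) {
      ct <- design$curve_intercept + design$curve_slope * log10(dilution_copies)
      if (dilution_jitter_sd > 0)
        ct <- ct + stats::rnorm(length(ct), 0, dilution_jitter_sd)
      data.frame(target = tg, copies = dilution_copies, ct = ct,
                 stringsAsFactors = FALSE)
    }))
    list(plate = plate, standards = standards, design = design)
  })
}

#' Simulate microarray spot tables from a synthetic design
#'
#' Uses the same generative core as [simulate_qpcr()]: per-sample copy
#' numbers become spot fluorescence via
#' `signal = background + array_gain * copies * noise`. Each sample is
#' hybridized to two successive subarrays (technical replicates); each
#' subarray carries 5 replicate spots of every capture and of Rluc; 8
#' subarrays fill a slide. Both channels (Cy3/Cy5) carry the same sample
#' with independent spot noise.
#'
#' @param design an [synthetic_design()] object.
#' @param n_subarrays_per_sample subarrays hybridized per sample.
#' @param spots_per_capture replicate spots per capture per subarray.
#' @return list with `spots`, `layout`, `samples` data.frames and the
#'   `design`.
#' @export
simulate_array <- function(design, n_subarrays_per_sample = 2L,
                           spots_per_capture = 5L) {
  stopifnot(inherits(design, "ur_synthetic_design"))
  with_preserved_rng(design$seed + 1L, {
    copies <- simulate_copies(design)
    samples <- unique(copies[, c("sample_id", "condition")])
    n_units <- nrow(samples) * n_subarrays_per_sample
    slide <- rep(seq_len(ceiling(n_units / 8L)), each = 8L)[seq_len(n_units)]
    sub <- ((seq_len(n_units) - 1L) %% 8L) + 1L
    unit_map <- data.frame(
      sample_id = rep(samples$sample_id, each = n_subarrays_per_sample),
      condition = rep(samples$condition, each = n_subarrays_per_sample),
      slide_id = paste0("S", slide), subarray = sub,
      stringsAsFactors = FALSE)
    captures <- c(design$targets, "Rluc")
    layout <- do.call(rbind, lapply(seq_along(captures), function(ci) {
      data.frame(subarray = rep(1:8, each = spots_per_capture),
                 row = ci,
                 col = rep(seq_len(spots_per_capture), times = 8L),
                 capture_id = captures[ci], stringsAsFactors = FALSE)
    }))
    spot_rows <- lapply(seq_len(nrow(unit_map)), function(u) {
      cp <- copies[copies$sample_id == unit_map$sample_id[u], ]
      cp <- cp[match(captures, cp$target), ]
      do.call(rbind, lapply(c("Cy3", "Cy5"), function(chan) {
        nspot <- spots_per_capture * length(captures)
        noise <- rlnorm_cv(nspot, design$spot_cv)
        data.frame(slide_id = unit_map$slide_id[u],
                   subarray = unit_map$subarray[u],
                   capture_id = rep(captures, each = spots_per_capture),
                   spot_replicate = rep(seq_len(spots_per_capture),
                                        times = length(captures)),
                   channel = chan,
                   signal = design$background_level +
                     design$array_gain * rep(cp$copies,
                                             each = spots_per_capture) * noise,
                   background = design$background_level,
                   stringsAsFactors = FALSE)
      }))
    })
    spots <- do.call(rbind, spot_rows)
    sheet <- do.call(rbind, lapply(c("Cy3", "Cy5"), function(chan) {
      data.frame(slide_id = unit_map$slide_id, subarray = unit_map$subarray,
                 channel = chan, sample_id = unit_map$sample_id,
                 condition = unit_map$condition, stringsAsFactors = FALSE)
    }))
    list(spots = spots, layout = layout, samples = sheet, design = design)
  })
}

#' Build a recovery scenario from the published effect-size table
#'
#' Returns a synthetic design for the full reporter library in which the
#' reporters listed for `treatment_label` carry their published log2 fold
#' inductions as ground truth and every other library reporter carries 0.
#' The `"Cadmium"` label uses the synthetic stand-in MRE/ARE magnitudes.
#'
#' @param treatment_label a treatment present in [table1_effects()].
#' @param n_targets library size.
#' @param ... further arguments passed to [synthetic_design()] (noise
#'   levels, replicate structure, seed).
#' @return an [synthetic_design()] object.
#' @export
#' @examples
#' d <- scenario_from_table1("Forskolin", seed = 7)
#' d$true_log2_fi[c("CREB", "ATF/1/2/3")]
scenario_from_table1 <- function(treatment_label, n_targets = 60L, ...) {
  tab <- table1_effects()
  rows <- tab[tab$treatment == treatment_label, , drop = FALSE]
  if (!nrow(rows))
    stop("unknown treatment label: ", treatment_label, call. = FALSE)
  targets <- default_library_targets(n_targets)
  synthetic_design(targets = targets, treatment = treatment_label,
                   true_log2_fi = stats::setNames(rows$log2_fi, rows$target),
                   ...)
}
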