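# Synthetic-data generator: ground-truth round trips, noise structure and
# published-scenario construction.

test_that("zero-noise simulations round-trip exactly through quantification", {
  null_design <- synthetic_design(targets = c("A", "B", "C"),
                                  replicate_cv = 0, inter_experiment_cv = 0,
                                  transfection_scale_sd = 0, spot_cv = 0,
                                  n_experiments = 1L, seed = 2L)
  sim <- simulate_qpcr(null_design)
  curves <- lapply(split(sim$standards, sim$standards$target),
                   fit_standard_curve)
  fi <- fold_induction(normalize_to_rluc(sim$plate, curves))
  expect_equal(fi$log2_fi, rep(0, 3), tolerance = 1e-9)

  d3 <- synthetic_design(targets = "A", true_log2_fi = c(A = 3),
                         replicate_cv = 0, inter_experiment_cv = 0,
                         transfection_scale_sd = 0, spot_cv = 0,
                         n_experiments = 1L, seed = 3L)
  sim <- simulate_qpcr(d3)
  curves <- lapply(split(sim$standards, sim$standards$target),
                   fit_standard_curve)
  fi <- fold_induction(normalize_to_rluc(sim$plate, curves))
  expect_equal(fi$log2_fi, 3.0, tolerance = 1e-9)
})

test_that("recovered fold inductions are invariant to transfection scaling", {
  fi_for <- function(ts_sd) {
    d <- synthetic_design(targets = "A", true_log2_fi = c(A = 2),
                          replicate_cv = 0, inter_experiment_cv = 0,
                          transfection_scale_sd = ts_sd, spot_cv = 0,
                          n_experiments = 1L, seed = 11L)
    sim <- simulate_qpcr(d)
    curves <- lapply(split(sim$standards, sim$standards$target),
                     fit_standard_curve)
    fold_induction(normalize_to_rluc(sim$plate, curves))$log2_fi
  }
  expect_equal(fi_for(0), 2.0, tolerance = 1e-9)
  expect_equal(fi_for(1.0), 2.0, tolerance = 1e-9)
})

test_that("replicate-level noise gives unbiased recovery at the stated n", {
  ests <- vapply(1:50, function(seed) {
    d <- synthetic_design(targets = "A", true_log2_fi = c(A = 2),
                          replicate_cv = 0.3, inter_experiment_cv = 0,
                          transfection_scale_sd = 0.3,
                          n_biological_replicates = 4L,
                          n_experiments = 1L, seed = seed)
    sim <- simulate_qpcr(d)
    curves <- lapply(split(sim$standards, sim$standards$target),
                     fit_standard_curve)
    fold_induction(normalize_to_rluc(sim$plate, curves))$log2_fi
  }, numeric(1))
  expect_lt(abs(mean(ests) - 2), 0.2)
})

test_that("array layout carries 5 replicate spots of every capture per subarray", {
  d <- synthetic_design(targets = c("A", "B"), n_experiments = 1L, seed = 4L)
  arr <- simulate_array(d)
  counts <- table(arr$layout$subarray, arr$layout$capture_id)
  expect_true(all(counts == 5L))
  expect_setequal(colnames(counts), c("A", "B", "Rluc"))
  spot_counts <- with(arr$spots,
                      table(paste(slide_id, subarray, channel, capture_id)))
  expect_true(all(spot_counts == 5L))
})

test_that("qPCR and array platforms concord on the same ground truth", {
  d <- synthetic_design(targets = c("A", "B"), true_log2_fi = c(A = 2),
                        inter_experiment_cv = 0, n_experiments = 1L,
                        seed = 17L)
  simq <- simulate_qpcr(d)
  curves <- lapply(split(simq$standards, simq$standards$target),
                   fit_standard_curve)
  fiq <- fold_induction(normalize_to_rluc(simq$plate, curves))
  arr <- simulate_array(d)
  fia <- array_fold_induction(
    normalize_array(summarize_spots(arr$spots, arr$samples, arr$layout)))
  for (tg in c("A", "B")) {
    dq <- fiq$log2_fi[fiq$target == tg]
    da <- fia$log2_fi[fia$target == tg]
    expect_lt(abs(dq - da), 1.0)
  }
})

test_that("published-treatment scenarios inject the right ground truth", {
  d <- scenario_from_table1("Forskolin", seed = 1L)
  nz <- names(d$true_log2_fi[d$true_log2_fi != 0])
  expect_setequal(nz, c("CREB", "ATF/1/2/3", "SRE/SRF"))
  expect_equal(unname(d$true_log2_fi["CREB"]), 13.6)
  expect_equal(length(d$targets), 60L)

  dg <- scenario_from_table1("8-bromo-cGMP", seed = 1L)
  expect_true(all(abs(dg$true_log2_fi) < 1))
  expect_equal(unname(dg$true_log2_fi["CREB"]), 0.3)

  dc <- scenario_from_table1("Cadmium", seed = 1L)
  expect_setequal(names(dc$true_log2_fi[dc$true_log2_fi != 0]),
                  c("MRE", "ARE"))

  expect_error(scenario_from_table1("NotATreatment"), "unknown")
})

test_that("wider replicate noise widens posterior credible intervals on average", {
  width_for <- function(cv, seed) {
    d <- synthetic_design(targets = "A", true_log2_fi = c(A = 2),
                          replicate_cv = cv, inter_experiment_cv = 0,
                          n_experiments = 1L, seed = seed)
    sim <- simulate_qpcr(d)
    curves <- lapply(split(sim$standards, sim$standards$target),
                     fit_standard_curve)
    expr <- normalize_to_rluc(sim$plate, curves)
    s <- summarize_posterior(fit_bayes_anova(expr, fast_spec(seed = seed)))
    s$ci_high - s$ci_low
  }
  lo <- mean(vapply(1:5, function(i) width_for(0.1, i), numeric(1)))
  hi <- mean(vapply(1:5, function(i) width_for(0.6, i), numeric(1)))
  expect_gt(hi, lo)
})
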