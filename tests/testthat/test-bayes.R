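# Bayesian ANOVA fitting, posterior summaries, significance rules and
# convergence diagnostics.

test_that("a noise-free constant offset concentrates the contrast posterior", {
  dat <- data.frame(log2_value = c(rep(5, 8), rep(8, 8)),
                    condition = rep(c("control", "treated"), each = 8),
                    target = "T1", experiment = 1L)
  f <- fit_bayes_anova(dat, fast_spec(seed = 4))
  s <- summarize_posterior(f)
  expect_equal(s$posterior_mean, 3.0, tolerance = 0.01)
  expect_lt(s$posterior_sd, 0.05)
  expect_equal(s$p_value, 1e-9)
})

test_that("chains are identical across runs with the same seed", {
  set.seed(8)
  dat <- data.frame(log2_value = rnorm(24, rep(c(0, 1), each = 12), 0.4),
                    condition = rep(c("control", "treated"), each = 12),
                    target = "T1", experiment = rep(1:3, 8))
  f1 <- fit_bayes_anova(dat, fast_spec(seed = 2))
  f2 <- fit_bayes_anova(dat, fast_spec(seed = 2))
  expect_identical(lapply(f1$samples, as.matrix),
                   lapply(f2$samples, as.matrix))
})

test_that("a null contrast is recovered near zero at the stated n and noise", {
  set.seed(42)
  y <- rnorm(16, 0, 0.2)
  dat <- data.frame(log2_value = y,
                    condition = rep(c("control", "treated"), each = 8),
                    target = "T1", experiment = 1L)
  s <- summarize_posterior(fit_bayes_anova(dat, fast_spec(seed = 6)))
  expect_lt(abs(s$posterior_mean), 0.25)
  # and the posterior tracks the realized sample contrast
  expect_equal(s$posterior_mean, mean(y[9:16]) - mean(y[1:8]),
               tolerance = 0.05)
})

test_that("with mild noise and large n the posterior mean matches the sample contrast", {
  set.seed(13)
  n <- 400
  y <- c(rnorm(n, 1, 0.3), rnorm(n, 3.2, 0.3))
  dat <- data.frame(log2_value = y,
                    condition = rep(c("control", "treated"), each = n),
                    target = "T1", experiment = 1L)
  s <- summarize_posterior(fit_bayes_anova(dat, fast_spec(seed = 9)))
  contrast <- mean(y[(n + 1):(2 * n)]) - mean(y[1:n])
  expect_equal(s$posterior_mean, contrast, tolerance = 1e-2)
})

test_that("the contrast flips sign under treated/control label exchange", {
  set.seed(2)
  dat <- data.frame(log2_value = rnorm(24, rep(c(0, 2), each = 12), 0.4),
                    condition = rep(c("control", "treated"), each = 12),
                    target = "T1", experiment = 1L)
  a <- summarize_posterior(fit_bayes_anova(dat, fast_spec(seed = 3)))
  b <- summarize_posterior(fit_bayes_anova(dat, fast_spec(seed = 3),
                                           treated = "control",
                                           control = "treated"))
  expect_equal(a$posterior_mean, -b$posterior_mean, tolerance = 0.05)
})

test_that("model validation rejects bad designs", {
  dat <- data.frame(log2_value = c(1, 2, 3), condition = c("control",
                    "control", "treated"), target = "T1", experiment = 1L)
  expect_error(fit_bayes_anova(dat, fast_spec()), "fewer than 2")
  dat2 <- data.frame(log2_value = c(1, NA, 2, 3),
                     condition = rep(c("control", "treated"), each = 2),
                     target = "T1", experiment = 1L)
  expect_error(fit_bayes_anova(dat2, fast_spec()), "non-finite")
  expect_error(model_spec("qpcr", chains = 1), "2 chains")
})

test_that("posterior tail p-values and credible intervals follow their definitions", {
  sym <- c(seq(-1, 1, length.out = 2000))
  s <- posterior_contrast_summary(sym)
  expect_gt(s$p_value, 0.99)
  expect_equal(s$posterior_mean, 0, tolerance = 1e-9)

  pos <- runif(2000, 0.5, 2)
  expect_equal(posterior_contrast_summary(pos)$p_value, 1e-9)

  pm <- rep(c(-1, 1), 1000)
  s <- posterior_contrast_summary(pm)
  expect_lt(s$ci_low, 0)
  expect_gt(s$ci_high, 0)
  expect_equal(s$posterior_mean, 0, tolerance = 1e-12)

  expect_error(posterior_contrast_summary(rnorm(10)), "too few")
})

test_that("significance calls apply the basal band, CrI and alpha rules jointly", {
  mk <- function(mean, lo, hi, p) {
    data.frame(target = "T", treatment = "x", posterior_mean = mean,
               posterior_sd = 0.3, ci_low = lo, ci_high = hi, p_value = p,
               n_effective = 1000, psrf = 1.0, converged = TRUE)
  }
  s <- call_significance(mk(0.9, 0.5, 1.3, 1e-9))
  expect_false(s$significant)
  expect_match(s$reasons, "within_basal_band")

  s <- call_significance(mk(3.8, 2.6, 5.0, 1e-9))
  expect_true(s$significant)
  expect_identical(s$reasons, "")

  s <- call_significance(mk(1.5, -0.2, 3.2, 0.04))
  expect_false(s$significant)
  expect_match(s$reasons, "ci_crosses_zero")

  # error bars re-entering the band disqualify even a large mean
  s <- call_significance(mk(2.0, 0.8, 3.2, 1e-9))
  expect_false(s$significant)
  expect_match(s$reasons, "within_basal_band")

  s <- call_significance(mk(-3.0, -4.0, -2.0, 1e-9))
  expect_true(s$significant)

  s <- call_significance(mk(2.0, 1.2, 2.8, 0.2))
  expect_false(s$significant)
  expect_identical(s$reasons, "p_above_alpha")
})

test_that("scale-reduction diagnostics match the reference implementation", {
  set.seed(91)
  chains <- lapply(1:3, function(i) rnorm(500))
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  ref <- as.numeric(coda::gelman.diag(ml, autoburnin = FALSE,
                                      transform = FALSE)$psrf[1, 1])
  expect_equal(gelman_rubin(chains), ref, tolerance = 1e-6)
  expect_lt(gelman_rubin(chains), 1.05)

  apart <- list(rnorm(500, 0), rnorm(500, 10))
  expect_gt(gelman_rubin(apart), 1.1)
  ml2 <- coda::mcmc.list(lapply(apart, coda::mcmc))
  ref2 <- as.numeric(coda::gelman.diag(ml2, autoburnin = FALSE,
                                       transform = FALSE)$psrf[1, 1])
  expect_equal(gelman_rubin(apart), ref2, tolerance = 1e-6)

  d <- check_convergence(ml2)
  expect_true(d$flagged)
  expect_error(check_convergence(coda::mcmc.list(coda::mcmc(rnorm(100)))),
               "2 chains")
})
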