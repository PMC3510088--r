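# Hierarchical Bayesian ANOVA for log2 normalized reporter expression,
# fitted by Gibbs sampling (JAGS), with posterior fold-induction summaries,
# tail p-values and significance calls.

#' Specify a Bayesian ANOVA model for reporter data
#'
#' The qPCR model is a three-way ANOVA on log2 normalized copy number:
#' grand mean + target effect + per-target treatment contrast + experiment
#' random intercept + residual. The microarray model is a two-way
#' repeated-measures ANOVA: the experiment factor is replaced by a random
#' intercept per hybridization unit (slide/subarray), the unit on which
#' all captures of one sample are measured together. In both, the
#' per-target treatment contrast *is* the mean log2 fold induction whose
#' posterior is reported. Fixed effects carry normal(0, 10^2) priors;
#' standard deviations carry half-Cauchy(0, 2.5) priors.
#'
#' @param platform `"qpcr"` or `"microarray"`.
#' @param chains number of MCMC chains (>= 2).
#' @param iterations post-burn-in iterations per chain.
#' @param burn_in discarded initial iterations per chain.
#' @param adapt JAGS adaptation iterations.
#' @param thin thinning interval.
#' @param seed integer seed; per-chain RNGs are derived from it.
#' @return object of class `ur_model_spec`.
#' @export
model_spec <- function(platform = c("qpcr", "microarray"),
                       chains = 4L, iterations = 5000L, burn_in = 1000L,
                       adapt = 500L, thin = 1L, seed = 1L) {
  platform <- match.arg(platform)
  spec <- list(platform = platform, chains = as.integer(chains),
               iterations = as.integer(iterations),
               burn_in = as.integer(burn_in), adapt = as.integer(adapt),
               thin = as.integer(thin), seed = as.integer(seed))
  if (spec$chains < 2) stop("at least 2 chains required", call. = FALSE)
  if (spec$iterations <= 0 || spec$burn_in < 0)
    stop("iterations must be positive and burn_in non-negative", call. = FALSE)
  class(spec) <- "ur_model_spec"
  spec
}

.jags_anova <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu + a[target[i]] + d[target[i]] * treated[i]%s, tau)
  }
  mu ~ dnorm(0, 1.0E-2)
  for (j in 1:NT) {
    a[j] ~ dnorm(0, 1.0E-2)
    d[j] ~ dnorm(0, 1.0E-2)
  }
%s
  sigma ~ dt(0, 0.16, 1) T(1.0E-3,)
  tau <- pow(sigma, -2)
}"

.jags_ranef <- "
  for (k in 1:NG) { g[k] ~ dnorm(0, tau_g) }
  sigma_g ~ dt(0, 0.16, 1) T(1.0E-3,)
  tau_g <- pow(sigma_g, -2)
"

#' Fit the Bayesian ANOVA to log2 normalized observations
#'
#' @param data data.frame with columns `log2_value`, `condition`, `target`
#'   and, depending on platform, `experiment` (qPCR) or `unit`
#'   (microarray). Exactly two condition levels are expected.
#' @param spec an [model_spec()] object.
#' @param treated,control condition labels.
#' @return object of class `ur_bayes_fit` carrying the per-target contrast
#'   samples (`coda::mcmc.list`), target names and the spec.
#' @export
fit_bayes_anova <- function(data, spec, treated = "treated",
                            control = "control") {
  stopifnot(inherits(spec, "ur_model_spec"))
  req <- c("log2_value", "condition", "target",
           if (spec$platform == "qpcr") "experiment" else "unit")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(data$log2_value)))
    stop("non-finite log2 observations", call. = FALSE)
  if (!all(data$condition %in% c(treated, control)))
    stop("condition labels must be '", treated, "' or '", control, "'",
         call. = FALSE)
  targets <- sort(unique(data$target))
  cell_n <- table(data$target, data$condition)
  bad <- which(cell_n < 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("fewer than 2 observations in cell (%s, %s)",
                 rownames(cell_n)[bad[1, 1]], colnames(cell_n)[bad[1, 2]]),
         call. = FALSE)

  grp <- if (spec$platform == "qpcr") data$experiment else data$unit
  grp <- factor(grp)
  use_ranef <- nlevels(grp) > 1
  jd <- list(y = data$log2_value,
             target = as.integer(factor(data$target, levels = targets)),
             treated = as.integer(data$condition == treated),
             N = nrow(data), NT = length(targets))
  if (use_ranef) {
    jd$group <- as.integer(grp)
    jd$NG <- nlevels(grp)
  }
  model_str <- sprintf(.jags_anova,
                       if (use_ranef) " + g[group[i]]" else "",
                       if (use_ranef) .jags_ranef else "")
  inits <- lapply(seq_len(spec$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         # keep derived per-chain seeds inside 32-bit integer range
         .RNG.seed = (spec$seed %% 2147483L) * 1000L + ch)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = jd,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = spec$adapt, quiet = TRUE)
  if (spec$burn_in > 0) update(jm, spec$burn_in, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "d", n.iter = spec$iterations,
                              thin = spec$thin, progress.bar = "none")
  fit <- list(samples = samp, targets = targets, spec = spec,
              treated = treated, control = control,
              n_obs = nrow(data))
  class(fit) <- "ur_bayes_fit"
  fit
}

#' @export
print.ur_bayes_fit <- function(x, ...) {
  cat(sprintf("Bayesian ANOVA fit (%s): %d targets, %d obs, %d chains x %d iter\n",
              x$spec$platform, length(x$targets), x$n_obs,
              x$spec$chains, x$spec$iterations))
  invisible(x)
}

# Pooled posterior draws of one target's contrast across chains.
contrast_draws <- function(fit, target) {
  j <- match(target, fit$targets)
  if (is.na(j)) stop("unknown target: ", target, call. = FALSE)
  par <- if (length(fit$targets) == 1) "d" else sprintf("d[%d]", j)
  unlist(lapply(fit$samples, function(ch) as.numeric(ch[, par])))
}

#' Posterior summary of a fold-induction contrast from raw draws
#'
#' Computes the posterior mean, central 95% credible interval, posterior
#' standard deviation and two-sided tail p-value
#' 2 min(P(d <= 0), P(d >= 0)), floored at the smallest reported
#' resolution of 1e-9.
#'
#' @param draws numeric vector of posterior contrast samples.
#' @param level credible-interval mass.
#' @param p_floor smallest reportable posterior tail p-value.
#' @return one-row data.frame.
#' @export
posterior_contrast_summary <- function(draws, level = 0.95, p_floor = 1e-9) {
  if (length(draws) < 40)
    stop("too few posterior samples for credible-interval quantiles",
         call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(draws, c(alpha, 1 - alpha)))
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  data.frame(posterior_mean = mean(draws),
             posterior_sd = stats::sd(draws),
             ci_low = ci[1], ci_high = ci[2],
             p_value = min(1, max(p_floor, p)))
}

#' Summarize fold-induction posteriors for all (or one) target
#'
#' @param fit an [fit_bayes_anova()] object.
#' @param target optional target name; default summarizes all.
#' @param treatment label recorded in the output (the treatment whose
#'   contrast was modelled).
#' @return data.frame with one row per target: posterior mean log2 fold
#'   induction, 95% credible interval, posterior SD, tail p-value,
#'   effective sample size and a convergence flag (split-chain scale
#'   reduction <= 1.1).
#' @export
summarize_posterior <- function(fit, target = NULL, treatment = "treated") {
  targets <- if (is.null(target)) fit$targets else target
  diag <- check_convergence(fit)
  rows <- lapply(targets, function(tg) {
    draws <- contrast_draws(fit, tg)
    s <- posterior_contrast_summary(draws)
    j <- match(tg, fit$targets)
    par <- if (length(fit$targets) == 1) "d" else sprintf("d[%d]", j)
    drow <- diag[diag$parameter == par, , drop = FALSE]
    cbind(data.frame(target = tg, treatment = treatment,
                     stringsAsFactors = FALSE),
          s,
          data.frame(n_effective = drow$n_effective,
                     psrf = drow$psrf,
                     converged = !drow$flagged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call significance for fold-induction posterior summaries
#'
#' A reporter/treatment cell is significant only when all of the
#' following hold: the posterior mean lies outside the basal-variation
#' band (default log2 values in \[-1, +1\], attributed to
#' treatment-independent variation); the 95% credible interval excludes
#' zero; the interval bound nearer zero also lies outside the basal band
#' (error bars entering the band disqualify); and the posterior tail
#' p-value is at most `alpha`. Failed rules are listed in `reasons`
#' (comma-separated among `within_basal_band`, `ci_crosses_zero`,
#' `p_above_alpha`); `significant` is true iff `reasons` is empty.
#'
#' @param summary data.frame from [summarize_posterior()].
#' @param basal_band numeric length-2 basal-variation band in log2 units.
#' @param alpha posterior p-value threshold.
#' @return `summary` with `significant` and `reasons` columns appended.
#' @export
call_significance <- function(summary, basal_band = c(-1, 1), alpha = 0.05) {
  stopifnot(all(c("posterior_mean", "ci_low", "ci_high", "p_value") %in%
                  names(summary)))
  reasons <- vapply(seq_len(nrow(summary)), function(i) {
    m <- summary$posterior_mean[i]
    lo <- summary$ci_low[i]; hi <- summary$ci_high[i]
    r <- character(0)
    inner <- if (m >= 0) lo else hi   # interval bound nearer zero
    if ((m >= basal_band[1] && m <= basal_band[2]) ||
        (inner >= basal_band[1] && inner <= basal_band[2]))
      r <- c(r, "within_basal_band")
    if (lo <= 0 && hi >= 0) r <- c(r, "ci_crosses_zero")
    if (summary$p_value[i] > alpha) r <- c(r, "p_above_alpha")
    paste(r, collapse = ",")
  }, character(1))
  summary$significant <- reasons == ""
  summary$reasons <- reasons
  summary
}

#' MCMC convergence diagnostics
#'
#' Computes the potential scale reduction factor (Gelman-Rubin statistic,
#' with the sampling-variability degrees-of-freedom correction) and the
#' effective sample size for every monitored contrast, flagging parameters
#' with scale reduction above 1.1.
#'
#' @param fit an [fit_bayes_anova()] object or a `coda::mcmc.list`.
#' @param threshold scale-reduction flag threshold.
#' @return data.frame with `parameter`, `psrf`, `n_effective`, `flagged`.
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  samples <- if (inherits(fit, "ur_bayes_fit")) fit$samples else fit
  if (!inherits(samples, "mcmc.list"))
    samples <- coda::as.mcmc.list(samples)
  if (length(samples) < 2)
    stop("convergence diagnostics require at least 2 chains", call. = FALSE)
  if (is.null(dim(samples[[1]])))
    samples <- coda::as.mcmc.list(lapply(samples, function(ch) {
      m <- coda::mcmc(matrix(as.numeric(ch), ncol = 1,
                             dimnames = list(NULL, "par")))
      m
    }))
  pars <- colnames(samples[[1]])
  psrf <- vapply(pars, function(p) {
    gelman_rubin(lapply(samples, function(ch) as.numeric(ch[, p])))
  }, numeric(1))
  ess <- vapply(pars, function(p) {
    unname(coda::effectiveSize(samples[, p]))
  }, numeric(1))
  data.frame(parameter = pars, psrf = unname(psrf),
             n_effective = unname(ess),
             flagged = unname(psrf) > threshold,
             stringsAsFactors = FALSE)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Univariate PSRF with the degrees-of-freedom correction
#' sqrt((d+3)/(d+1) * Vhat/W), where Vhat combines within- and
#' between-chain variance and d is estimated from the sampling variance of
#' Vhat.
#'
#' @param chains list of equal-length numeric vectors, one per chain.
#' @return numeric scalar.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("need at least 2 chains", call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  xbar <- vapply(chains, mean, numeric(1))
  s2 <- vapply(chains, stats::var, numeric(1))
  W <- mean(s2)
  B <- n * stats::var(xbar)
  muhat <- mean(xbar)
  sigma2 <- (n - 1) * W / n + B / n
  Vhat <- sigma2 + B / (m * n)
  var_w <- stats::var(s2) / m
  var_b <- 2 * B^2 / (m - 1)
  cov_wb <- (n / m) * (stats::cov(s2, xbar^2) - 2 * muhat * stats::cov(s2, xbar))
  var_V <- ((n - 1) / n)^2 * var_w + ((m + 1) / (m * n))^2 * var_b +
    2 * ((m + 1) * (n - 1) / (m * n^2)) * cov_wb
  d <- 2 * Vhat^2 / var_V
  sqrt((d + 3) / (d + 1) * Vhat / W)
}
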