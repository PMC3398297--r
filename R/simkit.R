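# Simulation framework: the interaction trait model, type I error and power
# experiments, and the analytic optimal-factor-effect proxy.

#' Residual-error specification for trait simulation
#'
#' The trait model's error term is either standard normal or chi-square
#' shaped, the latter probing how each test copes with skewed residuals.
#' A chi-square error with `standardize = TRUE` (the default) is centred and
#' scaled to mean 0 and variance 1, `(chi^2_df - df) / sqrt(2 df)`, so that
#' power comparisons across error families are made at equal error variance;
#' type I error is unaffected by the scaling either way.
#'
#' @param family `"normal"` or `"chisq"`.
#' @param df Degrees of freedom of the chi-square error (ignored for normal).
#' @param standardize Centre and scale a chi-square error to unit variance.
#' @return An object of class `"error_spec"`.
#' @export
error_spec <- function(family = c("normal", "chisq"), df = 1L, standardize = TRUE) {
  family <- match.arg(family)
  if (family == "chisq") {
    .assert_scalar_number(df, "df", lo = 1)
    df <- as.integer(df)
  }
  structure(list(family = family, df = df, standardize = isTRUE(standardize)),
            class = "error_spec")
}

.r_error <- function(n, spec) {
  if (spec$family == "normal") return(rnorm(n))
  e <- rchisq(n, df = spec$df) - spec$df
  if (spec$standardize) e <- e / sqrt(2 * spec$df)
  e
}

# (variance, fourth central moment) of the error term
.error_moments <- function(spec) {
  if (spec$family == "normal") return(c(var = 1, m4 = 3))
  df <- spec$df
  if (spec$standardize) c(var = 1, m4 = 3 + 12 / df)
  else c(var = 2 * df, m4 = 12 * df * (df + 4))
}

#' Interaction trait model
#'
#' Parameter bundle for the generative model
#' `y = mu + beta_g * g + beta_F * F + beta_gF * g * F + eps`,
#' where `g ~ Binomial(2, p_B)` is the count of the interacting B allele,
#' `F ~ N(mu_F, sigma2_F)` is an (unmeasured) quantitative factor, and `eps`
#' follows [error_spec()].  `g`, `F` and `eps` are mutually independent.  A
#' non-zero interaction `beta_gF` makes the conditional trait variance
#' `(beta_F + beta_gF * g)^2 * sigma2_F + var(eps)` depend on allele count,
#' which is exactly what the variance-heterogeneity tests detect.
#'
#' @param mu Trait intercept.
#' @param beta_g Direct (mean) effect of the SNP.
#' @param beta_F Main effect of the interacting factor.
#' @param beta_gF Interaction effect between SNP and factor.
#' @param p_B Frequency of the interacting B allele, in `[0, 1]`.
#' @param mu_F Mean of the factor.
#' @param sigma2_F Variance of the factor (> 0).
#' @param error An [error_spec()].
#' @return An object of class `"simulation_model"`.
#' @export
simulation_model <- function(mu = 0, beta_g = 0, beta_F = 0, beta_gF = 0,
                             p_B, mu_F = 0, sigma2_F = 1,
                             error = error_spec("normal")) {
  .assert_scalar_number(p_B, "p_B", 0, 1)
  .assert_scalar_number(sigma2_F, "sigma2_F", lo = .Machine$double.xmin)
  for (nm in c("mu", "beta_g", "beta_F", "beta_gF", "mu_F"))
    .assert_scalar_number(get(nm), nm)
  if (!inherits(error, "error_spec")) vq_config("'error' must be an error_spec()")
  structure(list(mu = mu, beta_g = beta_g, beta_F = beta_F, beta_gF = beta_gF,
                 p_B = p_B, mu_F = mu_F, sigma2_F = sigma2_F, error = error),
            class = "simulation_model")
}

# Conditional trait variance v(g) for g = 0, 1, 2
.conditional_variance <- function(model) {
  em <- .error_moments(model$error)
  (model$beta_F + model$beta_gF * (0:2))^2 * model$sigma2_F + em["var"]
}

#' Simulate genotypes at a biallelic SNP
#'
#' `mode = "binomial"` draws allele counts i.i.d. from `Binomial(2, p_B)`
#' (Hardy-Weinberg proportions).  `mode = "fixed_counts"` instead produces
#' exactly `round(2 * n * p_B)` heterozygotes with the remainder homozygous
#' for the major allele — the construction used for extreme-rarity scenarios
#' where the allele frequency is specified through an exact heterozygote
#' count and a binomial draw would often be monomorphic.  Fixed-count
#' genotypes are placed deterministically (carriers first); since the trait
#' is simulated independently per individual, carrier placement does not
#' affect any test statistic's distribution.
#'
#' @param n Number of individuals.
#' @param p_B Frequency of the B allele in `[0, 1]`.
#' @param mode `"binomial"` or `"fixed_counts"`.
#' @param seed Optional integer seed (`set.seed` locally before drawing).
#' @return Integer vector of length `n` with values in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, p_B, mode = c("binomial", "fixed_counts"),
                               seed = NULL) {
  mode <- match.arg(mode)
  .assert_scalar_number(n, "n", lo = 1)
  .assert_scalar_number(p_B, "p_B", 0, 1)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "binomial") {
    rbinom(n, size = 2L, prob = p_B)
  } else {
    m <- round(2 * n * p_B)
    if (m > n) vq_config("fixed_counts mode requires 2 * n * p_B <= n")
    c(rep(1L, m), rep(0L, n - m))
  }
}

#' Simulate a quantitative trait under the interaction model
#'
#' Draws the factor `F` and the error term independently of the supplied
#' genotypes and returns
#' `y = mu + beta_g * g + beta_F * F + beta_gF * g * F + eps`.
#'
#' @param model A [simulation_model()].
#' @param g Integer genotype vector without missing values.
#' @param seed Optional integer seed.
#' @return Numeric trait vector of `length(g)`.
#' @export
simulate_trait <- function(model, g, seed = NULL) {
  if (!inherits(model, "simulation_model")) vq_config("'model' must be a simulation_model()")
  if (anyNA(g)) vq_config("'g' must not contain missing values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(g)
  f <- rnorm(n, mean = model$mu_F, sd = sqrt(model$sigma2_F))
  eps <- .r_error(n, model$error)
  model$mu + model$beta_g * g + (model$beta_F + model$beta_gF * g) * f + eps
}

#' Configuration of a rejection-rate experiment
#'
#' Bundles a trait model with the Monte-Carlo settings of a type I error or
#' power experiment: cohort size, replicate count, rejection threshold, which
#' test to apply, the genotype-generation mode and the base seed.
#'
#' Reproducibility: replicate `r` reseeds the generator with
#' `(1000003 * seed + r) mod (2^31 - 1)`, so any single replicate can be
#' regenerated in isolation, the full experiment is invariant to execution
#' order, and nearby base seeds draw disjoint replicate streams.
#'
#' @param model A [simulation_model()].
#' @param n_samples Individuals per replicate (>= 10).
#' @param n_replicates Number of independent replicates (>= 1).
#' @param alpha Rejection threshold for the p-value, in (0, 1].
#' @param test `"svlm"` or `"levene"`.
#' @param seed Non-negative integer base seed.
#' @param genotype_mode Passed to [simulate_genotypes()].
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(model, n_samples = 10000L, n_replicates = 1000L,
                              alpha = 0.05, test = c("svlm", "levene"),
                              seed = 1L,
                              genotype_mode = c("binomial", "fixed_counts")) {
  test <- match.arg(test)
  genotype_mode <- match.arg(genotype_mode)
  if (!inherits(model, "simulation_model")) vq_config("'model' must be a simulation_model()")
  .assert_scalar_number(n_samples, "n_samples", lo = 10)
  .assert_scalar_number(n_replicates, "n_replicates", lo = 1)
  .assert_scalar_number(alpha, "alpha", lo = 1e-12, hi = 1)
  .assert_scalar_number(seed, "seed", lo = 0, hi = 2^31 - 1)
  structure(list(model = model, n_samples = as.integer(n_samples),
                 n_replicates = as.integer(n_replicates), alpha = alpha,
                 test = test, seed = as.integer(seed),
                 genotype_mode = genotype_mode),
            class = "experiment_config")
}

# Shared Monte-Carlo engine: fraction of replicates with p <= alpha.
.run_rates <- function(config) {
  model <- config$model
  n <- config$n_samples
  fixed_g <- if (config$genotype_mode == "fixed_counts")
    simulate_genotypes(n, model$p_B, "fixed_counts") else NULL
  p_fun <- if (config$test == "svlm") .svlm_p_fast else .levene_p_fast
  n_reject <- 0L
  n_skipped <- 0L
  for (r in seq_len(config$n_replicates)) {
    # multiplicative spreading keeps the replicate streams of nearby base
    # seeds disjoint while any single replicate stays reproducible
    set.seed((config$seed * 1000003 + r) %% 2147483647)
    g <- if (is.null(fixed_g)) rbinom(n, 2L, model$p_B) else fixed_g
    y <- simulate_trait(model, g)
    p <- p_fun(y, g)
    if (is.na(p)) n_skipped <- n_skipped + 1L
    else if (p <= config$alpha) n_reject <- n_reject + 1L
  }
  n_eff <- config$n_replicates - n_skipped
  rate <- if (n_eff > 0) n_reject / n_eff else NA_real_
  structure(
    list(rate = rate,
         se = if (n_eff > 0) sqrt(rate * (1 - rate) / n_eff) else NA_real_,
         n_replicates = n_eff, n_skipped = n_skipped),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rejection rate %.5f +/- %.5f (SE) over %d replicates (%d skipped)\n",
              x$rate, x$se, x$n_replicates, x$n_skipped))
  invisible(x)
}

#' Empirical type I error of a variance-heterogeneity test
#'
#' Simulates `n_replicates` cohorts under the null of homogeneous genotypic
#' variance (no factor effect, no interaction), applies the configured test
#' to each, and returns the fraction of replicates rejecting at
#' `p <= alpha`.  Replicates in which the test is undefined (for instance a
#' monomorphic binomial draw at a rare allele) are skipped and counted in
#' `n_skipped`; a test that never ran cannot reject, so skipped replicates
#' are excluded from the denominator.
#'
#' @param config An [experiment_config()] whose model has
#'   `beta_F = beta_gF = 0` (anything else is not a null model and is
#'   rejected; use [estimate_power()] instead).
#' @return A `"rate_estimate"`: `rate`, binomial `se`, effective
#'   `n_replicates` and `n_skipped`.
#' @export
type1_error <- function(config) {
  if (!inherits(config, "experiment_config")) vq_config("'config' must be an experiment_config()")
  if (config$model$beta_F != 0 || config$model$beta_gF != 0)
    vq_config("type I error requires a null model: beta_F = beta_gF = 0")
  .run_rates(config)
}

#' Empirical power of a variance-heterogeneity test
#'
#' Same Monte-Carlo machinery as [type1_error()] but without the null-model
#' restriction: the rejection fraction under an alternative (typically
#' `beta_gF != 0`) is the test's power at level `alpha`.
#'
#' @param config An [experiment_config()].
#' @return A `"rate_estimate"`.
#' @export
estimate_power <- function(config) {
  if (!inherits(config, "experiment_config")) vq_config("'config' must be an experiment_config()")
  .run_rates(config)
}

# Analytic power proxy for the SVLM stage-2 slope under the interaction
# model: squared population regression slope of the conditional variance
# v(g) = (beta_F + beta_gF g)^2 sigma2_F + var(eps) on g, divided by the
# population variance of the squared residual u = ((beta_F + beta_gF g) F +
# eps)^2.  Monotone transformations of the noncentrality do not move the
# arg-max, so this surrogate identifies the power-maximising beta_F.
# The error enters through its variance and a Gaussian-shaped fourth moment
# (m4 = 3 var^2): with the variances fixed, the designed optimum then
# depends on the interaction effect alone and is shared across error
# families, as in the power experiments this reconstructs.
.svlm_power_proxy <- function(beta_F, beta_gF, p_B, sigma2_F = 1,
                              error = error_spec("normal")) {
  w <- dbinom(0:2, 2, p_B)
  gbar <- 2 * p_B
  varg <- 2 * p_B * (1 - p_B)
  if (varg == 0) vq_config("p_B of 0 or 1 leaves no genotype variation")
  s2e <- .error_moments(error)[["var"]]
  e4 <- 3 * s2e^2
  a <- beta_F + beta_gF * (0:2)
  s2f <- a^2 * sigma2_F                       # variance of the factor term by genotype
  v <- s2f + s2e                              # conditional variance of the trait
  slope <- sum(w * (0:2 - gbar) * v) / varg
  ew4 <- 3 * s2f^2 + 6 * s2f * s2e + e4      # E[(aF + eps)^4 | g]
  var_u <- sum(w * (ew4 - v^2)) + sum(w * v^2) - sum(w * v)^2
  slope^2 / var_u
}

#' Optimal main effect of the interacting factor
#'
#' For a fixed interaction effect the power of a variance-heterogeneity test
#' is not monotone in the factor's main effect `beta_F`: the genotypic
#' variance difference `(beta_F + beta_gF g)^2 sigma2_F` grows with
#' `|beta_F|`, but so does the noise of the squared residuals, and an
#' interior `beta_F` maximises power.  This function scans a grid of
#' candidate `beta_F` values and returns the one maximising an analytic
#' noncentrality surrogate for the SVLM stage-2 slope (see Details); ties
#' are broken toward the smaller `|beta_F|`.
#'
#' @details The surrogate is the squared population regression slope of the
#' conditional variance on allele count divided by the population variance of
#' the squared residual, computed exactly over the `Binomial(2, p_B)`
#' genotype distribution.  The residual's fourth moment is taken
#' Gaussian-shaped at the error's variance, so with the factor and error
#' variances fixed the designed optimum depends on the interaction effect
#' alone and the same `beta_F` serves every error family — skewed errors
#' change realized power, not the designed factor effect.  The proxy is
#' deterministic, so power grids built on it are reproducible without nested
#' simulation.
#'
#' @param beta_gF Non-zero interaction effect.
#' @param model_base A [simulation_model()] supplying `p_B`, `sigma2_F` and
#'   the error family (its `beta_F`/`beta_gF` are ignored).
#' @param grid Candidate `beta_F` values.
#' @return The grid value of `beta_F` with maximal surrogate power.
#' @export
optimal_factor_effect <- function(beta_gF, model_base,
                                  grid = seq(-3, 3, by = 0.01)) {
  if (!inherits(model_base, "simulation_model")) vq_config("'model_base' must be a simulation_model()")
  .assert_scalar_number(beta_gF, "beta_gF")
  if (beta_gF == 0)
    vq_undefined("beta_gF = 0: the variance-difference proxy is identically zero")
  if (length(grid) == 0L) vq_config("'grid' must be non-empty")
  vals <- vapply(grid, .svlm_power_proxy, numeric(1),
                 beta_gF = beta_gF, p_B = model_base$p_B,
                 sigma2_F = model_base$sigma2_F, error = model_base$error)
  best <- which(vals == max(vals))
  if (length(best) > 1L) best <- best[which.min(abs(grid[best]))]
  grid[best]
}

#' Power of both tests along an interaction-effect grid
#'
#' Convenience wrapper reproducing the standard power experiment: for each
#' interaction effect in `beta_gF_grid` the factor's main effect is set to
#' [optimal_factor_effect()] and the rejection rate of the requested test is
#' estimated by simulation.
#'
#' @param beta_gF_grid Interaction effects to scan.
#' @param test `"svlm"` or `"levene"`.
#' @param p_B Interacting-allele frequency.
#' @param error An [error_spec()].
#' @param n_samples,n_replicates,alpha,seed,genotype_mode Passed to
#'   [experiment_config()]; each grid point uses seed
#'   `seed + 100000 * (point index - 1)` so points are independent.
#' @return A data frame with one row per grid point: `test`, `n`, `p_B`,
#'   `beta_g`, `beta_F`, `beta_gF`, `error_family`, `df`, `n_replicates`,
#'   `rate`, `se`, `n_skipped`, `seed`.
#' @export
power_curve <- function(beta_gF_grid, test = c("svlm", "levene"), p_B = 0.4,
                        error = error_spec("normal"), n_samples = 10000L,
                        n_replicates = 1000L, alpha = 0.05, seed = 1L,
                        genotype_mode = "binomial") {
  test <- match.arg(test)
  rows <- lapply(seq_along(beta_gF_grid), function(i) {
    b_gF <- beta_gF_grid[i]
    base <- simulation_model(p_B = p_B, error = error)
    b_F <- if (b_gF == 0) 0 else optimal_factor_effect(b_gF, base)
    model <- simulation_model(beta_F = b_F, beta_gF = b_gF, p_B = p_B, error = error)
    cfg <- experiment_config(model, n_samples = n_samples,
                             n_replicates = n_replicates, alpha = alpha,
                             test = test, seed = seed + 100000L * (i - 1L),
                             genotype_mode = genotype_mode)
    est <- estimate_power(cfg)
    experiment_row(cfg, est)
  })
  do.call(rbind, rows)
}

#' Flatten an experiment and its rate estimate to one result row
#'
#' @param config The [experiment_config()] that was run.
#' @param est The `"rate_estimate"` it produced.
#' @return A one-row data frame with the standard result columns (see
#'   [power_curve()]).
#' @export
experiment_row <- function(config, est) {
  m <- config$model
  data.frame(
    test = config$test, n = config$n_samples, p_B = m$p_B,
    beta_g = m$beta_g, beta_F = m$beta_F, beta_gF = m$beta_gF,
    error_family = m$error$family,
    df = if (m$error$family == "chisq") m$error$df else NA_integer_,
    n_replicates = est$n_replicates, rate = est$rate, se = est$se,
    n_skipped = est$n_skipped, seed = config$seed,
    stringsAsFactors = FALSE
  )
}

#' Read an experiment configuration from a key-value file
#'
#' The file holds one `key = value` pair per line; `#` starts a comment.
#' Recognised keys: `test`, `n_samples`, `n_replicates`, `alpha`, `seed`,
#' `genotype_mode`, `p_B`, `mu`, `beta_g`, `beta_F`, `beta_gF`, `mu_F`,
#' `sigma2_F`, `error_family`, `error_df`, `error_standardize`.  Unknown keys
#' raise an error; `p_B` is required, everything else has the package
#' defaults.
#'
#' @param path Path to the configuration file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) vq_config(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    vq_config(sprintf("malformed config line: '%s'", lines[bad][1]))
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- c("test", "n_samples", "n_replicates", "alpha", "seed",
             "genotype_mode", "p_B", "mu", "beta_g", "beta_F", "beta_gF",
             "mu_F", "sigma2_F", "error_family", "error_df",
             "error_standardize")
  if (any(!keys %in% known))
    vq_config(sprintf("unknown config key(s): %s",
                      paste(setdiff(keys, known), collapse = ", ")))
  if (anyDuplicated(keys))
    vq_config("duplicate config keys")
  get_val <- function(key, default) if (key %in% keys) vals[keys == key] else default
  num <- function(key, default) as.numeric(get_val(key, default))
  err <- error_spec(
    family = get_val("error_family", "normal"),
    df = num("error_df", 1),
    standardize = !tolower(get_val("error_standardize", "true")) %in% c("false", "0", "no")
  )
  if (!"p_B" %in% keys) vq_config("config must set p_B")
  model <- simulation_model(
    mu = num("mu", 0), beta_g = num("beta_g", 0), beta_F = num("beta_F", 0),
    beta_gF = num("beta_gF", 0), p_B = num("p_B", NA), mu_F = num("mu_F", 0),
    sigma2_F = num("sigma2_F", 1), error = err
  )
  experiment_config(
    model,
    n_samples = num("n_samples", 10000), n_replicates = num("n_replicates", 1000),
    alpha = num("alpha", 0.05), test = get_val("test", "svlm"),
    seed = num("seed", 1), genotype_mode = get_val("genotype_mode", "binomial")
  )
}

#' Write experiment result rows as TSV
#'
#' Tab-separated, one header line, `NA` for missing; written atomically.
#'
#' @param results Data frame of result rows (e.g. from [power_curve()] or
#'   [experiment_row()]).
#' @param path Output path (`.gz` suffix compresses).
#' @return The path, invisibly.
#' @export
write_experiment_results <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L)
    vq_config("'results' must be a non-empty data frame")
  .atomic_write(path, function(tmp) {
    con <- if (.is_gz(path)) gzfile(tmp, "wb") else file(tmp, "wb")
    on.exit(close(con))
    write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}
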