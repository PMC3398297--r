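# Single-SNP variance-heterogeneity tests: the Brown-Forsythe (median-based
# Levene) test for hard genotype calls and the two-stage squared-residual
# regression test (SVLM) for imputed allele dosages.

# Core Brown-Forsythe computation on complete data; returns NULL when fewer
# than two genotype groups are present and NA statistic when the denominator
# vanishes.  Shared by the user-facing test and the simulation fast path.
.levene_core <- function(y, g) {
  ug <- sort(unique(g))
  k <- length(ug)
  if (k < 2L) return(NULL)
  N <- length(y)
  gi <- match(g, ug)
  Z <- numeric(N)
  zbar_j <- numeric(k)
  med_j <- numeric(k)
  n_j <- integer(k)
  for (j in seq_len(k)) {
    idx <- which(gi == j)
    med_j[j] <- median(y[idx])
    zj <- abs(y[idx] - med_j[j])
    Z[idx] <- zj
    zbar_j[j] <- mean(zj)
    n_j[j] <- length(idx)
  }
  zbar <- mean(Z)
  num <- (N - k) * sum(n_j * (zbar_j - zbar)^2)
  den <- (k - 1) * sum((Z - zbar_j[gi])^2)
  list(
    statistic = if (den > 0) num / den else NA_real_,
    df1 = k - 1L, df2 = N - k, k = k, n = N,
    group_levels = ug, group_sizes = n_j, group_medians = med_j
  )
}

#' Brown-Forsythe (median-based Levene) test for genotypic variance heterogeneity
#'
#' Tests whether the variance of a quantitative trait differs between genotype
#' groups, using absolute deviations from the group median.  With `Z_i = |y_i -
#' median(y in group of i)|` the statistic is the one-way ANOVA F ratio of the
#' `Z_i` across the `k` observed genotype groups,
#' `T^2 = (N-k) sum_j n_j (Zbar_j - Zbar)^2 / [(k-1) sum_i (Z_i - Zbar_{g_i})^2]`,
#' referred to an F distribution with `k - 1` and `N - k` degrees of freedom.
#' Genotype-dependent variance is the expected signature of a locus interacting
#' with an unmeasured environmental or genetic factor, so a small p-value flags
#' a candidate interacting variant (vQTL).
#'
#' Samples with a missing trait value or missing genotype are removed listwise.
#'
#' @param y Numeric vector of trait values; `NA` allowed.
#' @param g Integer vector of hard genotype calls, each `0`, `1` or `2` copies
#'   of the coded allele; `NA` allowed.  Same length as `y`.
#' @return An object of class `"levene_result"`: a list with `statistic`
#'   (`T^2`), `df1` (`k - 1`), `df2` (`N - k`), `p_value` (upper tail of the F
#'   distribution), and per-group audit fields `group_levels`, `group_sizes`
#'   and `group_medians`.
#' @section Errors: A locus with fewer than two genotype groups having at
#'   least two observations each raises a `"vq_monomorphic_error"`.  If every
#'   absolute deviation within every group is identical the statistic's
#'   denominator is zero and a `"vq_undefined_error"` is raised; this is
#'   deliberately distinct from the monomorphic case.
#' @examples
#' g <- rbinom(200, 2, 0.3)
#' y <- rnorm(200, sd = 1 + 0.4 * g)
#' brown_forsythe_levene(y, g)
#' @seealso [svlm_test()] for the dosage-based two-stage test.
#' @export
brown_forsythe_levene <- function(y, g) {
  if (length(y) != length(g))
    vq_config("'y' and 'g' must have the same length")
  ok <- !is.na(y) & !is.na(g)
  y <- as.numeric(y[ok])
  g <- g[ok]
  if (length(y) < 2L)
    vq_config("fewer than 2 observed samples after missing-data removal")
  if (!all(g %in% c(0, 1, 2)))
    vq_config("genotype calls must be 0, 1 or 2")
  tab <- table(g)
  if (sum(tab >= 2L) < 2L)
    vq_monomorphic("fewer than 2 genotype groups with >= 2 observations: locus is (effectively) monomorphic")
  core <- .levene_core(y, g)
  if (is.na(core$statistic))
    vq_undefined("Brown-Forsythe statistic undefined: zero within-group deviation spread")
  structure(
    list(
      statistic = core$statistic,
      df1 = core$df1, df2 = core$df2,
      p_value = pf(core$statistic, core$df1, core$df2, lower.tail = FALSE),
      n_used = core$n,
      group_levels = core$group_levels,
      group_sizes = core$group_sizes,
      group_medians = core$group_medians
    ),
    class = "levene_result"
  )
}

#' @export
print.levene_result <- function(x, ...) {
  cat("Brown-Forsythe variance-heterogeneity test\n")
  cat(sprintf("  T^2 = %.6g on df (%d, %d), p = %.6g\n",
              x$statistic, x$df1, x$df2, x$p_value))
  cat(sprintf("  groups (g = %s): n = %s; medians = %s\n",
              paste(x$group_levels, collapse = ", "),
              paste(x$group_sizes, collapse = ", "),
              paste(signif(x$group_medians, 4), collapse = ", ")))
  invisible(x)
}

# OLS via QR with classical (or HC1 sandwich) standard errors; returns the
# coefficient/SE/p for the column of interest plus residuals.
.ols_fit <- function(Z, y, coef_idx, robust = FALSE) {
  n <- nrow(Z)
  p <- ncol(Z)
  # a numerically constant response carries no signal: slope 0, p 1
  if (max(y) - min(y) <= 1e-12 * max(abs(y), 1)) {
    return(list(beta = 0, se = 0, p = 1, df = n - p,
                residuals = y - mean(y)))
  }
  qrz <- qr(Z)
  if (qrz$rank < p)
    vq_rank("design matrix is rank deficient")
  beta <- qr.coef(qrz, y)
  r <- as.numeric(y - Z %*% beta)
  df <- n - p
  XtXinv <- chol2inv(qr.R(qrz))
  if (robust) {
    # HC1 heteroskedasticity-consistent covariance
    meat <- crossprod(Z * r)
    vc <- XtXinv %*% meat %*% XtXinv * n / df
  } else {
    s2 <- sum(r^2) / df
    vc <- XtXinv * s2
  }
  se <- unname(sqrt(diag(vc))[coef_idx])
  b <- unname(beta[coef_idx])
  if (se == 0) {
    p_val <- if (b == 0) 1 else 0
  } else {
    p_val <- 2 * pt(-abs(b / se), df)
  }
  list(beta = b, se = se, p = p_val, df = df, residuals = r)
}

#' SVLM: squared-residual regression test for variance heterogeneity
#'
#' Two-stage test of genotype-dependent trait variance that accepts imputed
#' allele dosages.  Stage 1 regresses the trait on the dosage (and any
#' covariates) by ordinary least squares, removing any mean effect of the SNP.
#' Stage 2 regresses the squared stage-1 residuals on the dosage alone and
#' tests the slope.  Because the conditional mean of the squared residual
#' equals the conditional variance of the trait, a non-zero stage-2 slope is
#' evidence that trait variance changes with allele count — the screening
#' signature of an interacting locus.  Unlike group-based tests, nothing here
#' requires the genotype to be known with certainty, so fractional dosages in
#' `[0, 2]` are handled natively.
#'
#' Inference on both slopes uses the classical homoskedastic t-test: stage 1
#' on `n - 2 - ncol(X)` degrees of freedom, stage 2 on `n - 2` (dosage is the
#' only stage-2 regressor by default).  `robust = TRUE` switches both stages
#' to HC1 sandwich standard errors, which guards the stage-2 test against the
#' strong heteroskedasticity of squared residuals at the price of slightly
#' different finite-sample behaviour.
#'
#' @param y Numeric trait vector; `NA` allowed.
#' @param d Numeric dosage vector, each value in `[0, 2]` (expected count of
#'   the effect allele) or `NA`.  Hard calls in `{0, 1, 2}` are a special case.
#' @param X Optional covariate matrix or data frame (samples in rows).
#'   Constant columns (after missing-data removal) are dropped with a warning.
#' @param robust Use HC1 sandwich standard errors in both stages.
#' @param covariates_stage2 Carry `X` into the stage-2 design as well
#'   (default `FALSE`: stage 2 is intercept + dosage only).
#' @return An object of class `"svlm_result"`: list with `stage1_beta`,
#'   `stage1_se`, `stage1_p` (mean model), `stage2_beta`, `stage2_se`,
#'   `stage2_p` (variance model), and `n_used`.
#' @section Errors: constant dosage raises `"vq_monomorphic_error"`; too few
#'   samples for the requested design raises `"vq_rank_error"`.
#' @examples
#' d <- runif(300, 0, 2)
#' y <- rnorm(300, sd = sqrt(1 + 0.5 * d))
#' svlm_test(y, d)
#' @seealso [brown_forsythe_levene()], [hard_call()]
#' @export
svlm_test <- function(y, d, X = NULL, robust = FALSE, covariates_stage2 = FALSE) {
  if (length(y) != length(d))
    vq_config("'y' and 'd' must have the same length")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != length(y))
      vq_config("'X' must have one row per sample")
    storage.mode(X) <- "double"
  }
  ok <- !is.na(y) & !is.na(d)
  if (!is.null(X)) ok <- ok & complete.cases(X)
  y <- as.numeric(y[ok])
  d <- as.numeric(d[ok])
  n <- length(y)
  if (n < 3L)
    vq_config("fewer than 3 complete samples")
  if (any(d < 0 | d > 2))
    vq_config("dosages must lie in [0, 2]")
  if (max(d) == min(d))
    vq_monomorphic("dosage is constant: locus is monomorphic")
  if (!is.null(X)) {
    X <- X[ok, , drop = FALSE]
    keep <- apply(X, 2L, function(col) max(col) > min(col))
    if (!all(keep)) {
      warning(sprintf("dropping constant covariate column(s): %s",
                      paste(colnames(X)[!keep], collapse = ", ")))
      X <- X[, keep, drop = FALSE]
    }
    if (ncol(X) == 0L) X <- NULL
  }
  p1 <- 2L + if (is.null(X)) 0L else ncol(X)
  if (n <= p1)
    vq_rank(sprintf("n_used (%d) must exceed the number of fitted parameters (%d)", n, p1))
  Z1 <- cbind(`(Intercept)` = 1, dose = d, X)
  s1 <- .ols_fit(Z1, y, coef_idx = 2L, robust = robust)
  u <- s1$residuals^2
  Z2 <- if (covariates_stage2) Z1 else cbind(`(Intercept)` = 1, dose = d)
  if (n <= ncol(Z2))
    vq_rank("too few samples for the stage-2 design")
  s2 <- .ols_fit(Z2, u, coef_idx = 2L, robust = robust)
  structure(
    list(
      stage1_beta = s1$beta, stage1_se = s1$se, stage1_p = s1$p,
      stage2_beta = s2$beta, stage2_se = s2$se, stage2_p = s2$p,
      n_used = n
    ),
    class = "svlm_result"
  )
}

#' @export
print.svlm_result <- function(x, ...) {
  cat("SVLM variance-heterogeneity test (n =", x$n_used, ")\n")
  cat(sprintf("  stage 1 (trait mean):      beta = %.6g, se = %.6g, p = %.6g\n",
              x$stage1_beta, x$stage1_se, x$stage1_p))
  cat(sprintf("  stage 2 (trait variance):  beta = %.6g, se = %.6g, p = %.6g\n",
              x$stage2_beta, x$stage2_se, x$stage2_p))
  invisible(x)
}

#' Convert imputed dosages to hard genotype calls
#'
#' Rounds each dosage to the nearest genotype in `{0, 1, 2}` and sets the call
#' to missing when the dosage is further than `max_distance` from that
#' integer, i.e. when the imputation is too uncertain for a group-based test.
#' A dosage exactly midway between two integers (x.5) rounds up, and a
#' distance exactly equal to `max_distance` is kept; both rules are
#' deterministic so repeated conversions agree.
#'
#' @param d Numeric dosage vector in `[0, 2]`; `NA` allowed and preserved.
#' @param max_distance Maximum tolerated distance from the nearest integer,
#'   in `[0, 0.5]`.  `0.5` calls every dosage; smaller values leave uncertain
#'   dosages uncalled.
#' @return Integer vector of calls in `{0, 1, 2}` with `NA` for uncalled.
#' @examples
#' hard_call(c(0.02, 0.97, 1.5, 1.2), max_distance = 0.1)
#' @export
hard_call <- function(d, max_distance = 0.5) {
  .assert_scalar_number(max_distance, "max_distance", 0, 0.5)
  d <- as.numeric(d)
  if (any(d < 0 | d > 2, na.rm = TRUE))
    vq_config("dosages must lie in [0, 2]")
  nearest <- pmin(floor(d + 0.5), 2)   # x.5 rounds up; floor(2.5) capped at 2
  out <- as.integer(nearest)
  # small epsilon so a distance exactly at the cutoff survives FP noise
  out[!is.na(d) & abs(d - nearest) > max_distance + 1e-9] <- NA_integer_
  out
}

# ---- fast paths used by the simulation engine ------------------------------
# Closed-form single-predictor regressions; no validation, complete data
# assumed.  Returns NA for a monomorphic/degenerate replicate so the caller
# can skip it.

.svlm_p_fast <- function(y, g) {
  n <- length(y)
  gc <- g - mean(g)
  Sgg <- sum(gc * gc)
  if (Sgg == 0) return(NA_real_)
  b1 <- sum(gc * y) / Sgg
  r <- y - mean(y) - b1 * gc
  u <- r * r
  if (max(u) - min(u) <= 1e-12 * max(u, 1)) return(1)
  uc <- u - mean(u)
  b2 <- sum(gc * uc) / Sgg
  rss <- sum(uc * uc) - b2 * b2 * Sgg
  df <- n - 2L
  if (rss <= 0) return(if (b2 == 0) 1 else 0)
  tval <- b2 / sqrt(rss / df / Sgg)
  2 * pt(-abs(tval), df)
}

.levene_p_fast <- function(y, g) {
  core <- .levene_core(y, g)
  if (is.null(core) || is.na(core$statistic)) return(NA_real_)
  pf(core$statistic, core$df1, core$df2, lower.tail = FALSE)
}
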