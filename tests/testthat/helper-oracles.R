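# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths: the Levene oracle goes through lm()/anova()
# on the transformed data, the OLS oracle solves the normal equations
# directly.

# One-way ANOVA F on absolute deviations from group medians, via generic
# least squares.
oracle_levene <- function(y, g) {
  meds <- tapply(y, g, median)
  z <- abs(y - meds[as.character(g)])
  fit <- lm(z ~ factor(g))
  a <- anova(fit)
  list(statistic = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
       p_value = a$`Pr(>F)`[1])
}

# Explicit normal-equations OLS: coefficient, classical SE and two-sided
# t-test p for one column of the design.
oracle_ols <- function(Z, y, idx) {
  ZtZ <- crossprod(Z)
  beta <- solve(ZtZ, crossprod(Z, y))
  r <- y - Z %*% beta
  df <- nrow(Z) - ncol(Z)
  s2 <- sum(r^2) / df
  se <- unname(sqrt(diag(solve(ZtZ)) * s2)[idx])
  b <- unname(beta[idx])
  list(beta = b, se = se, p = 2 * pt(-abs(b / se), df), residuals = as.numeric(r))
}

# The two SVLM stages as two independent sequential generic fits.
oracle_svlm <- function(y, d, X = NULL) {
  Z1 <- cbind(1, d, X)
  s1 <- oracle_ols(Z1, y, 2L)
  s2 <- oracle_ols(cbind(1, d), s1$residuals^2, 2L)
  list(stage1 = s1, stage2 = s2)
}

# Small random dosage matrix with reproducible contents.
make_dosage_fixture <- function(n_snp = 5, n_sample = 8, seed = 1,
                                na_frac = 0) {
  set.seed(seed)
  dose <- matrix(round(runif(n_snp * n_sample, 0, 2), 4), n_snp, n_sample)
  if (na_frac > 0)
    dose[sample(length(dose), ceiling(na_frac * length(dose)))] <- NA
  dosage_matrix(dose,
                snp_ids = sprintf("rs%04d", seq_len(n_snp)),
                effect_allele = rep(c("A", "C", "G", "T"), length.out = n_snp),
                other_allele = rep(c("G", "T", "A", "C"), length.out = n_snp),
                samples = sprintf("S%02d", seq_len(n_sample)))
}
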