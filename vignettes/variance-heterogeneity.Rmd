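---
title: "Variance-heterogeneity testing for interaction screening: models, simulations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-heterogeneity testing for interaction screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vqtlscan)
```

## Why test variances?

A locus that interacts with an unmeasured environmental or genetic factor
leaves a footprint in the *variance* of a quantitative trait conditional on
genotype, even when the factor itself is never observed: carriers of the
interacting allele respond to the hidden factor, so their trait values
spread more widely. Scanning the genome for genotype-dependent variance
(vQTL analysis) therefore screens for potentially interacting loci with one
test per SNP — the same multiple-testing burden as an ordinary GWAS, instead
of the combinatorial explosion of testing interaction models directly.
`vqtlscan` implements two such tests and the simulation machinery needed to
characterise them.

## The two tests

**Brown–Forsythe (median-based Levene) test.** For hard genotype calls
$g_i \in \{0,1,2\}$, let $Z_i = |y_i - \tilde y_{g_i}|$ be the absolute
deviation of individual $i$'s trait value from the *median* of its genotype
group. The statistic is the one-way ANOVA F ratio of the $Z_i$ across the
$k$ observed groups,

$$T^2 \;=\; \frac{(N-k)\sum_j n_j(\bar Z_{j\cdot}-\bar Z_{\cdot\cdot})^2}
                  {(k-1)\sum_i (Z_i-\bar Z_{g_i\cdot})^2},$$

referred to $F(k-1,\,N-k)$; for large $N$ this is indistinguishable from
$\chi^2_{k-1}/(k-1)$. Using the group median rather than the mean is what
makes the test robust to skewed traits. The test needs every observation
assigned to a definite group, which is why it cannot consume imputed
dosages directly.

**SVLM (squared-residual regression).** Since
$\mathrm{Var}(Y\mid g) = E[(Y - E[Y\mid g])^2 \mid g]$, estimating
conditional variances is the same problem as estimating conditional means
of squared residuals. Stage 1 regresses the trait on the allele dosage
(plus covariates) by OLS, removing any mean effect of the SNP; stage 2
regresses the squared stage-1 residuals on the dosage and tests its slope.
Everything is linear regression, so fractional dosages in $[0,2]$ — the
expected allele counts produced by imputation — need no special treatment,
and per-cohort results can be meta-analysed with standard inverse-variance
tools.

### Inference choices

The stage-2 slope is tested with the classical homoskedastic t-test on
$n-2$ degrees of freedom (stage 1 on $n-2-\mathrm{ncol}(X)$). The field's
descriptions of this procedure say "regression analysis" and no more, so we
took the simplest reading; squared residuals are of course heteroskedastic
under the alternative, and `robust = TRUE` switches both stages to HC1
sandwich errors for users who prefer that. The default stage-2 design is
intercept + dosage only — the SNP is the predictor of interest and stage 1
has already absorbed covariate mean effects — with `covariates_stage2 =
TRUE` available when covariates plausibly affect the variance too.

Degenerate inputs are classified, not silently propagated: a locus with
fewer than two informative genotype groups raises a *monomorphic* error,
while a defined grouping whose within-group deviations have zero spread
(the $T^2$ denominator vanishes) raises a distinct *undefined* error. In a
genome-wide scan these become per-SNP `status` values rather than aborting
the run. A numerically constant stage-2 response (squared residuals equal
to machine precision) is reported as slope 0 with p = 1, since such data
carry no variance signal either way. Group medians for even-sized groups
use the midpoint of the central order statistics; `hard_call()` rounds
dosages to the nearest genotype with a configurable maximum distance,
rounds x.5 up, and keeps a distance exactly at the cutoff (with a 1e-9
epsilon so floating-point representation cannot flip a call).

## The simulation model

Traits are generated as

$$y_i \;=\; \mu + \beta_g g_i + \beta_F F_i + \beta_{gF}\, g_i F_i + \varepsilon_i,$$

with $g_i \sim \mathrm{Binomial}(2, P_B)$, $F_i \sim N(\mu_F, \sigma^2_F)$
and $\varepsilon_i$ either standard normal or chi-square shaped, all
mutually independent. Defaults are $\mu=\mu_F=0$, $\sigma^2_F=1$; the
defaults of the experiment layer are cohorts of $n=10{,}000$ individuals,
rejection at $p \le 0.05$, allele frequency $P_B = 0.4$, 20,000 replicates
for type I error and 1,000 for power — the standard operating conditions
for these tests. Conditional on genotype the model implies

$$\mathrm{Var}(y \mid g) \;=\; (\beta_F + \beta_{gF}\, g)^2\sigma^2_F + \sigma^2_\varepsilon,$$

so $\beta_{gF} \ne 0$ produces exactly the variance heterogeneity the tests
look for; with $\beta_F, \beta_{gF} > 0$ the variance increases with each
copy of the interacting allele.

Chi-square errors (df 1 or 5) probe sensitivity to skewness. They are
centred and scaled to unit variance by default,
$\varepsilon = (\chi^2_{df}-df)/\sqrt{2\,df}$, so that every error family
enters with $\sigma^2_\varepsilon = 1$ and power comparisons are made at
equal noise; type I error is invariant to this scaling, so the null results
do not depend on the choice. Skewness is scale-invariant
($\sqrt{8/df}$ either way), which is the property that actually
differentiates the tests.

**Genotype generation.** Binomial mode draws Hardy–Weinberg genotypes
i.i.d. For the extreme-rarity scenarios, frequencies are specified through
exact heterozygote counts (10 carriers in 10,000 means $P_B = 5\times
10^{-4}$), and a binomial draw at such frequencies would often be
monomorphic; `fixed_counts` mode therefore places exactly
$\mathrm{round}(2 n P_B)$ heterozygotes with the remainder homozygous
major. Placement is deterministic (carriers first): the trait is simulated
i.i.d. per individual, so carrier positions cannot affect any test
statistic's distribution, and determinism keeps replicates reproducible.

**Reproducibility.** Replicate $r$ of an experiment reseeds the generator
with $(1000003\cdot\text{seed} + r) \bmod (2^{31}-1)$, so any single replicate can be
regenerated in isolation; multi-point experiments (power grids, the
low-frequency series) offset base seeds by 100,000 per grid point so the
streams never overlap. Replicates where the test is undefined are skipped
and reported in `n_skipped`; a test that never ran cannot reject, so they
leave the denominator, and the binomial standard error uses the effective
replicate count.

## The optimal factor effect

Power to detect an interaction of effect $\beta_{gF}$ is not monotone in
the factor's main effect $\beta_F$: the between-genotype variance contrast
$(\beta_F+\beta_{gF}g)^2\sigma_F^2$ grows with $|\beta_F|$, but so does the
noise of the squared residuals, and an interior $\beta_F$ maximises power.
`optimal_factor_effect()` maximises a deterministic surrogate over a grid:
the squared population regression slope of $\mathrm{Var}(y\mid g)$ on $g$
(over the exact binomial genotype distribution) divided by the population
variance of the squared residual. The residual's fourth moment is taken
Gaussian-shaped at the error's variance, which makes the designed optimum a
function of the interaction effect alone once $\sigma^2_F$ and
$\sigma^2_\varepsilon$ are fixed to one — a single $\beta_F(\beta_{gF})$
curve serves every error family, mirroring how these power studies are
designed. The alternative (plugging in each family's own fourth moment)
would re-optimise SVLM for skewed errors and thereby mask precisely the
skewness sensitivity the comparison is meant to expose. Power experiments
built with `power_curve()` use this optimum by default; ties in the grid
search break toward smaller $|\beta_F|$, and the surrogate is undefined at
$\beta_{gF}=0$ (there is nothing to optimise), which raises an error rather
than returning an arbitrary value.

```{r optimal-effect}
base <- simulation_model(p_B = 0.4)
sapply(c(0.05, 0.1, 0.2, 0.3), optimal_factor_effect, model_base = base)
```

## What the simulations do and do not emulate

The generator reproduces the conditions under which these tests'
operating characteristics are usually reported: a single biallelic SNP in
Hardy–Weinberg proportions, an independent Gaussian factor, additive
allele coding, and i.i.d. errors of controlled skewness. It deliberately
does not simulate linkage disequilibrium between SNPs, covariate
confounding, pedigree/polygenic correlation (residuals from a mixed model
should be used for family data, with the variance scan run on those), or
mean–variance coupling of non-interaction origin (e.g. scale traits where
variance tracks the mean). Passing the packaged checks therefore
demonstrates correct behaviour of the tests under the stated model, not
robustness to those real-data complications; the Brown–Forsythe test's
median-based robustness and SVLM's regression framing are the design
features expected to carry over.

## Numerical and scale choices

Monte-Carlo scales in the shipped checks were chosen to keep the full
suite in the minutes range while leaving comparisons well inside their
tolerances: 5,000 replicates for type I error checks (three combined
binomial standard errors ≈ ±0.009 at a rate of 0.05) and 1,000 replicates
per power point, at the standard cohort size $n = 10{,}000$; the
`scripts/acceptance.R` report uses the full 20,000 replicates per
scenario. The power grid spans $\beta_{gF} \in
\{0.01, 0.02, 0.03, 0.04, 0.06, 0.08\}$, which covers the rise from
near-nominal rejection to near-certain detection at $n = 10{,}000$,
$P_B = 0.4$; the ordering comparison between the two tests is made
mid-grid at $\beta_{gF} = 0.06$, where neither test has saturated.

Regression uses QR decomposition throughout (no explicit matrix
inversion); the scan flags rather than suppresses loci whose smallest
hard-called genotype group falls below 80 — the count below which the
squared-residual test is known to turn conservative — and reports their
statistics anyway, since conservative is not invalid.

## Known limitations

- SVLM loses power relative to Brown–Forsythe when the error distribution
  is strongly skewed (squaring residuals amplifies heavy right tails); the
  package's own power experiments quantify this.
- Below roughly 80 carriers the SVLM type I error is conservative, not
  inflated; p-values near the detection threshold at such counts should be
  treated as lower bounds on significance.
- The dosage container is held in memory; biobank-scale inputs should be
  scanned in chunks by the caller (the per-SNP records are independent, so
  chunking is trivial and the output rows concatenate).
- Binary traits, exact small-sample permutation p-values and mixed-model
  adjustment are out of scope.
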