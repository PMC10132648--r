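---
title: "Joint multilevel modelling of systolic and diastolic blood pressure"
author: "bpjoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multilevel modelling of systolic and diastolic blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and its assumptions

`bpjoint` fits a bivariate two-level linear mixed model for systolic (SBP)
and diastolic (DBP) blood pressure, in mmHg, measured on women nested in
households. For woman $i$ in household $j$:

$$y_{1ij} = x_{ij}'\beta_1 + h_{1j} + \varepsilon_{1ij}, \qquad
  y_{2ij} = x_{ij}'\beta_2 + h_{2j} + \varepsilon_{2ij},$$

with household random intercepts $(h_{1j}, h_{2j})' \sim N(0, \Sigma_h)$ and
woman-level residuals $(\varepsilon_{1ij}, \varepsilon_{2ij})' \sim
N(0, \Sigma_e)$, both covariance matrices unstructured $2\times 2$. The
assumptions this encodes:

- the two outcomes share one covariate vector $x_{ij}$ and differ only in
  coefficients (per-outcome designs are out of scope);
- household effects are exchangeable across a household's women and
  independent across households;
- all random terms are Gaussian (checked via `residual_qq_data()` /
  `plot()`);
- households are independent — survey design features (enumeration-area
  clustering, sampling weights, strata) are deliberately not modelled.

The post-fit quantities are the household-level variance partition
coefficient per outcome, $\rho_k = \sigma^2_{hk} / (\sigma^2_{hk} +
\sigma^2_{ek})$ (equal to the ICC under random intercepts, reported as a
percent rounded to the nearest integer), the residual correlations
$\mathrm{corr}(h_1, h_2)$ and $\mathrm{corr}(\varepsilon_1, \varepsilon_2)$,
the per-coefficient Wald test of $\beta_{1k} = \beta_{2k}$ (which needs the
cross-outcome coefficient covariance and is therefore rejected for
univariate fits), the LRT against the single-level model ($\Sigma_h \equiv
0$, a 3-parameter restriction), and AIC/BIC.

## Estimation

Estimation is direct maximum likelihood. The marginal covariance of a
household's $2n$ stacked outcomes (outcome-major within woman) is
$V = I_n \otimes \Sigma_e + J_n \otimes \Sigma_h$, so with
$A = \Sigma_e$ and $B = \Sigma_e + n\Sigma_h$,

$$\log\det V = (n-1)\log\det A + \log\det B, \qquad
  V^{-1} = I \otimes A^{-1} + \tfrac1n J \otimes (B^{-1} - A^{-1}).$$

Because $V^{-1}$ depends on the data only through per-household sums, the
entire profiled likelihood reduces to a handful of cross-products
($X'X$, $X'Y$, $Y'Y$, and per-household-size analogues of the household
column sums) computed once per dataset; each variance-component iterate then
costs $O(p^2)$ regardless of the number of women. Fixed effects are profiled
out by generalized least squares at every iterate, and the two covariance
matrices are optimized by L-BFGS-B in a log-Cholesky parameterization
(unconstrained off-diagonal, log diagonal), which enforces positive
semi-definiteness by construction. The fixed-effect covariance is the
inverse GLS information at the optimum, and 95% intervals are symmetric Wald
intervals.

The historical estimation route for such models is iterative generalized
least squares (IGLS); for Gaussian models IGLS converges to the maximum
likelihood estimate, so direct ML is used here and IGLS is not reimplemented.
REML is not implemented.

Numerical choices:

- **Boundary handling.** The household-level log-Cholesky diagonal is
  bounded below at $\log(10^{-4})$ (variance floor $10^{-8}$), so
  $\Sigma_h = 0$ is reachable; fits that end on the floor carry a
  `boundary` flag. The single-level model is not optimized at all — with
  $\Sigma_h \equiv 0$ the MLE is per-outcome least squares with
  $\hat\Sigma_e = E'E/N$, used in closed form.
- **Starting values.** $\Sigma_e$ from the pooled within-household
  covariance of per-outcome OLS residuals; $\Sigma_h$ from the
  household-mean ANOVA estimator, eigenvalue-clipped to positive
  definiteness.
- **Convergence.** L-BFGS-B with `factr = 1e3` (relative objective
  reduction of about $2\times10^{-13}$), finite-difference step $10^{-5}$,
  at most 500 iterations; the `converged` flag is the optimizer's exit
  status. At these tolerances the univariate fits agree with an independent
  mixed-model implementation (`lme4::lmer`, ML) to $10^{-5}$ in
  log-likelihood in the test suite.
- **Identifiability.** With mostly single-woman households, $\Sigma_h$ is
  identified mainly by the multi-woman households; every fit records their
  count (`n_multiwoman`) so the analyst can see how much information the
  household level actually has. This weak identification is visible in the
  household-level residual correlation, whose replicate-to-replicate spread
  is several times that of the woman-level one.
- **LRT reference.** The LRT degrees of freedom for the $\Sigma_h = 0$
  comparison are taken as 3 (the plain parameter-count difference). The
  null hypothesis places variances on the boundary of the parameter space,
  so the naive $\chi^2_3$ p-value is conservative; every result carries a
  note saying so, and no boundary-mixture correction is applied.
- **BIC.** $\mathrm{BIC} = -2\ell + k\log N$ with $N$ the number of women
  (level-1 units), not households.

## The synthetic-data generator

`default_sim_config()` encodes the study conditions the package targets:

- **3727 households**, each with 1, 2 or 3 eligible women with probabilities
  0.76 / 0.21 / 0.03 — chosen so the expected cohort is ≈4744 women at the
  observed women-to-household ratio of ≈1.27 (the size distribution itself
  is not published);
- **ten categorical risk factors** (three woman-level: age group, obesity,
  education; seven household-level: cooking fuel, wealth, water source,
  toilet type, household size class, wall type, vegetable consumption) with
  category probabilities equal to the published cohort frequencies, encoded
  as exact count ratios so each probability table sums to one at machine
  precision;
- **fixed effects** equal to the published joint-model point estimates
  (e.g. +15.85 mmHg SBP and +10.05 mmHg DBP for ages 45–49; +5.10 / +4.20
  for obesity);
- **covariance components** with household variances 38.91 / 16.37 mmHg²
  and correlation 0.81, woman-level variances 224.49 / 101.75 mmHg² and
  correlation 0.73 — implying a marginal SBP–DBP correlation of ≈0.74 and
  household VPCs of 15% / 14%;
- **intercepts 112 / 72 mmHg** for the all-reference woman: intercepts are
  not published, so these are clinically plausible reference-group means,
  configurable like everything else;
- **ten regions** assigned uniformly (regional sample sizes are not
  published), and an ever-told-hypertension flag drawn as an independent
  Bernoulli(0.069), used only by descriptives and maps.

What the generator deliberately does **not** emulate: covariate
correlations (factors are sampled independently — real wealth, fuel and
education are correlated), two-stage enumeration-area sampling and its
weights, any dependence of the ever-told flag on measured pressure, repeated
blood-pressure measurements, and regional heterogeneity in risk. Passing
parameter-recovery tests therefore show the estimator is correct *under the
model*, not that the model is adequate for any particular real survey; the
mapping stage on generated data shows mechanism, not geography.

## Simulation sizes used by the test suite

The test suite exercises the estimator at three scales, chosen to make each
claim sharp while keeping a full run in a few minutes: oracle equivalence of
the structured likelihood against a dense construction on 100 random small
instances (≤ 12 households); study-scale parameter recovery and model
comparison at the full 3727-household configuration (single fit, and 100
replicates for the selection rates, with the recovery seed fixed at 1);
and operating-characteristic simulations (type-I error of the equality test
at 500 replicates of 500 households; interval coverage at 200 replicates of
1000 households) under a reduced one-covariate configuration that keeps the
published covariance truth but shrinks the design, since those two
properties concern the variance machinery, not the covariate layout.

One finding from the model-comparison replicates is worth recording: with
the generating components above, the single-vs-multilevel LRT statistic
centres near 39 (sd ≈ 13). That comfortably clears the $p<0.001$ line
(≈96% of replicates) and the AIC margin (100%), but the BIC penalty for
three parameters at $N \approx 4744$ is $3\log N \approx 25.4$, which the
statistic exceeds in only ≈86% of replicates. Under these study conditions
BIC simply cannot be expected to select the household model in ≥95% of
replicates — a property of the singleton-dominated design and effect size,
not of the estimator — and the corresponding expectation in the acceptance
tests documents this by failing honestly rather than by inflating the
generating variance.

## Data handling choices

- Hypertension flags use inclusive thresholds: SBP ≥ 140 mmHg, DBP ≥ 90
  mmHg, combined = either.
- Printed percentages round half away from zero (one decimal for tables,
  nearest integer for VPCs), matching how the reference tabulations were
  rounded; base R's banker's rounding would disagree on exact halves.
- Boxplot outliers (values outside $[Q_1 - 1.5\,\mathrm{IQR},\;
  Q_3 + 1.5\,\mathrm{IQR}]$, quartiles by linear interpolation between order
  statistics, i.e. `quantile(type = 7)`) are flagged, never dropped.
- Missing values are handled by complete-case exclusion with a logged count.
- Region matching for choropleths is normalized exact-name matching
  (trimmed, case-insensitive); an unmatched region is an error, never a
  silent drop.

## Known limitations

Beyond the generator simplifications above: no survey weights or
design-based variance estimation; no three-level (community) extension; no
empirical-Bayes prediction of household effects; no REML or small-sample
degrees-of-freedom corrections; no boundary-corrected LRT p-values; the
equality-test table applies no multiplicity adjustment (flagged in the
output); and the Wald intervals rely on asymptotic normality, adequate at
survey scale but optimistic for small cohorts.
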