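---
title: "Meta-AHP composite risk indices: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-AHP composite risk indices: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaahp)
```

## The method in one page

`metaahp` chains three well-understood pieces of statistical machinery into
one pipeline for scoring geographic units by aggregate exposure to a set of
disease risk factors:

1. a **random-effects meta-analysis** that reduces each factor's published
   evidence base (odds/risk ratios with 95% CIs) to one pooled effect size;
2. the **Analytic Hierarchy Process**, which converts the vector of pooled
   effect sizes into normalized priority weights via the principal
   eigenvector of a pairwise comparison matrix, with Saaty's consistency
   check;
3. a **composite index** that applies those weights to regional exposure
   data, either as a weighted sum of 0/1 exposure indicators or of
   cross-regional z-scores, followed by percentile ranking and correlation
   against outcome rates.

The sections below document the modelling assumptions, the tunable
parameters and their defaults, the numerical choices, what the synthetic
generator does and does not emulate, and the places where the design was
genuinely open.

## Meta-analysis stage

**Model.** Each study's ratio estimate is analyzed on the log scale. The
standard error is recovered from the reported interval as
`se = (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975))`, which assumes the
interval is a symmetric 95% Wald interval on the log scale. Rows whose
log-scale CI half-widths differ by more than a factor of 1.5 are kept but
flagged, since a grossly asymmetric interval signals a non-Wald derivation
and an unreliable `se`. The pooled effect is the inverse-variance weighted
mean with random-effects weights `1/(se^2 + tau2)`; `tau2` is the
DerSimonian–Laird moment estimator, truncated at zero. DL is the standard
non-iterative choice for this design; the `method` argument accepts `"FE"`
so a fixed-effect analysis (or, by extension, another estimator) can be
slotted in. Heterogeneity is summarized by Cochran's Q (chi-square test on
`k - 1` df) and `I2 = max(0, (Q - df)/Q) * 100`.

**Inclusion rule.** Downstream AHP weighting is only meaningful for factors
whose pooled estimate exceeds 1, and the pipeline mirrors that at the study
level: rows with `estimate <= 1` are excluded with a logged reason code
(`require_gt1 = TRUE` by default). The test suite's estimator-calibration
checks disable the rule, because conditioning on `OR > 1` is a selection
effect that would bias any coverage assessment of the estimator itself.

**Publication-bias diagnostics.** Egger's test regresses the standardized
effect `y/se` on the precision `1/se` by OLS and t-tests the intercept on
`k - 2` df; Begg's test is the Kendall rank correlation between
variance-standardized deviations from the fixed-effect mean and the
sampling variances, with the normal-approximation p-value and no continuity
correction. Both need enough studies (`k >= 3` for Egger, and all-equal
precisions make the regressor degenerate); non-evaluable cases return `NA`
rather than a number. Two-sided tests are used throughout.

## AHP stage

**Comparison matrix.** The judgment step of classical AHP — an expert
choosing Saaty scores — is replaced by a deterministic map from pooled
effect sizes. Two modes:

* `continuous_ratio` (default): `a_ij = ES_i / ES_j`. Such a matrix is
  consistent by construction, so `lambda_max = n`, `CR = 0`, and the
  eigenvector weights equal `ES / sum(ES)` exactly. This makes the whole
  weighting step transparent and reproducible.
* `saaty_rounded`: ratios rounded to the nearest integer and clamped to
  `[1, 9]`, reciprocals below the diagonal. This emulates an analyst
  translating effect-size ratios onto the 1–9 verbal scale; rounding
  introduces (small) inconsistency, which is what the CR check is for.

Equal effect sizes yield a ratio of 1 (equal importance) and equal weights.
A published or elicited judgment matrix can bypass both modes: pass it
straight to `principal_eigenvector()`.

**Eigenvector and consistency.** The priority vector is the Perron
eigenvector, computed by power iteration from a uniform start with an L1
convergence tolerance of 1e-10 and a 10,000-iteration cap; positive
reciprocal matrices have a simple dominant positive eigenvalue, so
convergence is guaranteed and the cap is a safety net. Weights are
L1-normalized (sum to 1) because they are used as index coefficients.
`CI1 = (lambda_max - n)/(n - 1)`, `CR = CI1/RI(n)` with Saaty's tabulated
Random Index (n = 2..10; RI(2) = 0, so CR is defined as 0 there), and the
conventional CR < 0.1 acceptance rule. When a matrix fails the rule,
`derive_weights()` warns by default and can be configured to fail. The test
suite verifies the power iteration against R's dense eigensolver to 1e-8 on
random reciprocal matrices up to order 10.

**Published coefficient fixtures.** The package ships two named coefficient
vectors, `"LCRI"` (7 factors) and `"LCRI_IL"` (4 factors), as verbatim
fixtures. They cannot be re-derived from the corresponding published pooled
effect sizes by either deterministic mode — the generating judgment matrix
was never published — so they are treated as data, not as a target for the
derivation path; the derivation path is validated by the closed-form and
eigensolver properties above instead.

## Index stage

**Binary mode** evaluates `sum(w_f * I_f)` over 0/1 exposure indicators;
with weights summing to 1 the index is bounded in [0, 1], 0 meaning no
modelled exposure and 1 meaning all exposures present. **Z-score mode**
standardizes each factor column across regions with the sample (n − 1)
standard deviation and takes the weighted sum of z-scores. Pearson
correlations downstream are invariant to the (n) vs (n − 1) choice and to
standardizing the composite itself, so the table records both `composite`
and `composite_z`. Zero-variance factor columns are an error (their z-score
is undefined), named in the message. Missing region values are excluded
from the mean/sd and propagate to a missing composite for that region —
no silent imputation.

**Percentiles** use the average-rank convention `100 * rank / n`: it is
deterministic, tie-stable, monotone in the composite, and maps the maximum
to exactly 100. Any order-preserving transform of the composite yields
identical percentiles, which is why the choice of composite scaling cannot
affect the mapped ranks.

**Correlation and sensitivity.** Index validation uses sample Pearson
correlations with the two-sided t-test on `n - 2` df, pairwise deletion of
missing values, and a 0.05 significance flag with no multiple-testing
correction (the per-factor sensitivity table is descriptive; users wanting
family-wise control can apply `p.adjust` to the exported p-values).
Drop-one sensitivity removes a factor, re-derives weights on the survivors
— weights renormalize to 1 by construction — and reports index–outcome
correlations before and after side by side.

## Synthetic data: what it does and does not show

`gen_studies()` draws, per study, a true log effect from
`Normal(true_log_effect, tau2)`, a standard error uniformly from
`[se_low, se_high]`, and an observed log effect from `Normal(effect, se^2)`
— exactly the random-effects model the pooling stage assumes. Defaults
emulate a seven-factor evidence base of 52 studies (12 for the dominant
factor, 6–8 for the rest) with true effects at the magnitudes of a
lung-cancer-style factor set (one OR near 8.6, six between 1.2 and 1.8),
`tau2 = 0.05`, and `se` in [0.1, 0.5]. Rows with simulated `OR <= 1` are
emitted deliberately so the inclusion filter is exercised.

`gen_regions()` draws factor values per region (normal, or lognormal for
nonnegative right-skewed exposures like radon), computes the true composite
from ground-truth weights on z-scored factors, and generates outcomes as
`outcome = mean + sd * (rho * composite_z + sqrt(1 - rho^2) * noise)`,
planting a population correlation `rho` between the standardized composite
and each outcome. Defaults: 102 regions; smoking 18 ± 3.5 %, drinking
18 ± 3 %, PM2.5 9 ± 1.5 µg/m³, radon lognormal with mean 4.5 and sd 2
pCi/L; ground-truth weights = the 4-factor published fixture; `rho = 0.5`;
outcome scales 65 ± 10 (incidence) and 45 ± 8 (mortality) per 100,000.
These were chosen once as realistic magnitudes for a US-state county table.

Because the generator matches the estimator's assumptions, passing tests
demonstrate *internal* correctness — parameter recovery, CI coverage,
planted-correlation recovery, determinism — not robustness to real-data
pathologies: spatial autocorrelation between neighboring counties,
non-Wald or asymmetric published intervals, correlated exposures (smoking
and drinking co-vary in reality but are generated independently), outlier
regions, or outcome confounding by healthcare access. Conclusions about
real tables need the usual diagnostics on those tables.

## Numerical choices and degenerate inputs

* Power iteration: uniform start, L1 tolerance 1e-10, max 10,000
  iterations; non-convergence is an error carrying the iteration count.
* Reciprocity of input matrices is checked to 1e-6 before iterating.
* `tau2` and `I2` truncate at zero; `I2 = 0` when `Q = 0`.
* Ties in effect sizes give comparison entries of 1 and equal weights.
* `ci_low == ci_high` (zero SE) is a rejected row, not an infinite weight.
* All-equal composites: percentiles are all equal; the composite z-score
  divides by 1 instead of 0 and returns zeros.
* Test problem sizes (200 replicates for coverage, 500 seeds for
  correlation recovery, matrices up to order 10) keep the full suite under
  roughly ten seconds while leaving Monte-Carlo error well inside the
  asserted tolerances.

## Known limitations

* The AHP stage admits only factors with pooled estimates above 1;
  protective factors cannot enter the index.
* Weights depend only on effect-size magnitudes, not on regional exposure
  prevalence — a factor with a modest OR but huge prevalence variation can
  matter more in reality than its weight suggests.
* Binary mode imposes a single cut point per factor; curvilinear
  exposure–response shapes are out of scope.
* One criteria layer only: no group judgment aggregation, fuzzy AHP, or
  alternative-level hierarchies.
* The index is associational; correlations with outcome rates are not
  causal estimates and are vulnerable to ecological confounding.
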