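---
title: "Methods: county-level ecological regression of cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: county-level ecological regression of cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoincidence)
```

This vignette documents the statistical models behind `ecoincidence`, the
assumptions they rest on, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices made where conventions diverge. It states no empirical
result beyond what the package's own tests and acceptance script compute.

## The ecological design

All quantities are measured at the county level: the outcome is a
county's age-standardized incidence rate for one cancer, age group and
sex, and the predictors are county-level exposure summaries (typically
measured about a decade earlier, reflecting an assumed induction lag from
exposure to diagnosis). Associations estimated at this level describe
counties, not individuals; the package is a tool for hypothesis
generation about population exposures, not causal inference about
persons (the classic ecological-fallacy caveat).

Every variable — outcome and predictors — is z-scored (sample SD, n−1
denominator) before modelling, so all regression coefficients are
standardized: a bivariable slope equals the Pearson correlation exactly,
and multivariable coefficients are comparable in magnitude across
exposures. `standardize_columns()` records centers and scales for
reporting.

## Direct age standardization

For one county stratum with age bands $a$, case counts $c_a$, person-year
populations $n_a$ and standard-population weights $w_a$,

$$\text{rate} = 10^5 \sum_a \tilde w_a \frac{c_a}{n_a}, \qquad
  \tilde w_a = w_a \Big/ \sum_{a'} w_{a'},$$

where the sum runs over the bands present in the data. Renormalizing over
present bands makes the computation invariant to uniform weight rescaling
and handles partial age ranges (e.g. 25–49) without a separate weight
file per age group. A default table of 2000 U.S. standard-million
weights in 5-year bands ships as plain CSV configuration
(`us_standard_population()`); any `age_band, weight` table can be
substituted. Zero population in a present band is an error (the crude
rate is undefined), not a silent drop.

A stratum enters analysis only if the number of counties reporting
**strictly more than** `min_cases = 5` cumulative cases **strictly
exceeds** `min_fraction = 0.6` of the county total. Both inequalities are
strict; with 62 counties the smallest passing count is 38
(`inclusion_threshold(62)`), which is the worked value the rule is
calibrated against. The filter is monotone: relaxing either parameter
never removes a retained stratum (property-tested).

## Segmented log-linear trends

Annual series are modelled as continuous piecewise-linear functions of
calendar year on the log-rate scale (the joinpoint convention — segments
join, they do not jump). With hinge basis
$\log y_t = \beta_0 + \beta_1 (t - t_0) + \sum_j \gamma_j (t - \tau_j)_+$,
the slope of segment $i$ is $b_i = \beta_1 + \sum_{j \le i} \gamma_j$ and
the annual percent change is $\mathrm{APC}_i = 100(e^{b_i} - 1)$.
Confidence intervals and two-sided p-values are t-based on the fit's
covariance, transformed through the same exponential map.

The average annual percent change over a span weights segment slopes by
the number of years each segment contributes:
$\mathrm{AAPC} = 100\left(\exp\left(\sum w_i b_i / \sum w_i\right) - 1\right)$,
with variance from the delta method on the weighted slope,
$\mathbf a^\top \Sigma_b \mathbf a$ with $\mathbf a = \mathbf w / \sum w_i$.
The tooling that popularized AAPC does not pin down a single CI method;
the delta method was chosen here for its closed form and because it makes
the zero-joinpoint AAPC collapse exactly onto the single APC, interval
and all (unit-tested identity). A trend is classified `increasing` /
`decreasing` when the AAPC is significant at $\alpha = 0.05$, otherwise
`stable`.

**Model-size selection.** Candidate joinpoints are placed on observed
years; for each size $k \in \{0, \dots, k_\max\}$ (default $k_\max = 2$)
every admissible placement is fit and the minimum-RSS placement wins —
for the ~19-year series this grid *is* the exhaustive search, verified
against an independent enumeration oracle in the tests. Across sizes the
default is a sequential permutation test ($k$ vs $k+1$, default 499
permutations of the null-model residuals, advance while $p < 0.05$),
matching the convention of the standard joinpoint software; BIC with
$2(k+1)$ parameters per size is offered as a fast alternative.
`min_seg_obs = 3` observations per segment (endpoints included) is the
default admissibility constraint; it is configurable and not dictated by
theory.

**Degenerate fits.** A zero-residual fit has no residual variance to test
against; rather than fail, the package reports the documented limit:
$p \to 0$ for a nonzero slope, $p = 1$ for a zero slope, with intervals
collapsed to the point estimate. Zero-residual detection uses a relative
tolerance of $10^{-10}$ on the log-rate sum of squares. RSS inside BIC is
floored at $10^{-12}$ so perfect fits stay finite. Series too short for
even the smallest segmented model fall back to the 0-joinpoint fit with a
warning recorded in the selection trace.

## Two-stage association analysis

**Stage 1 — screening.** Each exposure is assessed by two OLS models: the
bivariable model, and a model adjusted for the forced race &
socio-economic covariates. A factor is pooled for stage 2 when either
two-sided p-value is below `p_threshold` (default 0.1; 0.2 and 0.3 are
the documented sensitivity settings, and pooling is provably monotone
across them). No multiple-testing correction is applied at this stage —
screening is deliberately permissive, and the cost of a false inclusion
is only a slightly larger stage-2 search. Missing exposure values are
handled by per-factor listwise deletion with the per-model n recorded;
each model uses its own complete cases. When the race covariate is itself
highly correlated with the factor under test (|r| strictly above 0.6, the
same threshold as the stage-2 conflict rule; configurable), it is dropped
from that factor's adjustment set — adjusting for a near-copy of the
exposure would estimate a meaningless partial effect.

**Stage 2 — decorrelated exhaustive selection.** Pairs of pooled
candidates (plus the spatial terms latitude and latitude², when present)
with |Pearson r| strictly above `conflict_r = 0.6` (0.5 in sensitivity
mode) may never share a model. The package enumerates the **maximal**
independent sets of this conflict graph. Enumerating only maximal sets is
lossless: every compatible set is a subset of some maximal one, and the
subsequent best-subset search examines every subset of each combination —
a coverage property tested exhaustively on random graphs up to 12 nodes.
Enumeration uses maximal cliques of the complement graph; node counts
above 40 raise an error suggesting a stricter threshold rather than an
open-ended computation.

Within each combination the search is exhaustive over all $2^p$ subsets
(guarded at $p \le 25$), each fit with the forced covariates always
included, scored by

$$\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + k \ln n,$$

the Gaussian profile-likelihood form with constants dropped (constants
cancel within a pool fit to the same data; BICs from other software may
differ by a constant). $k$ counts every estimated coefficient — the
intercept and the forced covariates included, since they are estimated
parameters; this too only shifts BICs by a constant within a pool that
shares a forced set. The subset scan works on the Gram matrix
(one `crossprod` of the full design, then a small Cholesky solve per
subset) and is verified against an lm-per-subset brute force on random
instances. A weak hierarchy admits latitude² only alongside latitude
(a quadratic without its linear term would pin the vertex of the
parabola at zero latitude, which is meaningless); rank-deficient subsets
are skipped and logged. Exact BIC ties break toward fewer variables, then
lexicographic variable names — an arbitrary but deterministic rule.

**Pooling and pruning.** The per-combination winners are pooled; models
with adjusted $R^2 = 1 - \frac{\mathrm{RSS}/(n-k)}{\mathrm{TSS}/(n-1)}$
below 0.3 are dropped (if none survive, the result is an explicit
"no model explains ≥ 30% of variation" outcome, not an error); duplicate
subsets are collapsed; nested models (strict subset relation between
selected sets) are grouped by connected components of the nesting
relation and only the lowest-BIC member of each group is kept — "group of
nested models" is not a formally standard object, so the
connected-component reading is documented here and pinned by a reference
implementation in the tests. Survivors are ranked by BIC; those within
ΔBIC < 2 of the best (strict, configurable) are flagged comparable and
reported together. Coefficients of reported models come from a plain lm
refit. Reported intervals are conditional on the selected model;
post-selection inference corrections are out of scope and the output
should be read accordingly.

A sensitivity mode (`race_as_candidate`) moves the percent-white
covariate from the forced set into the candidate pool, where it is
selected by BIC and subject to the conflict rule like any other variable.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which the pipeline's operating characteristics are measured.

* **Exposures** are jointly Gaussian with a block-diagonal correlation
  structure (equicorrelated blocks; PSD checked per block, rejecting
  $\rho < -1/(m-1)$ with the offending block named). Real county
  exposures are mixed-scale and non-Gaussian, but every analysis step
  operates on z-scored variables, so the Gaussian copula is the minimal
  structure the models assume. What is *not* emulated: the marginal
  distributions of real exposure variables and spatial autocorrelation
  between neighbouring counties. Passing recovery tests therefore show
  correctness of the machinery under the stated correlation structure,
  not robustness to spatial confounding.
* **Outcomes** are $y = \sum_i \beta_i z_i + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$, homoscedastic across counties — the
  assumption the linear models make. Real county rates are likely
  heteroscedastic (small-population counties have noisier rates); the
  default stays homoscedastic to match the model being tested.
  `generate_outcome()` reports the realized population
  $R^2 = \operatorname{Var}(X\beta) / (\operatorname{Var}(X\beta) + \sigma^2)$
  using the sample variance of the linear predictor on the realized
  design, so the calibration identity holds exactly and
  `noise_sd_for_r2()` inverts it exactly.
* **Case counts** are Poisson with mean $\text{rate} \times n_a / 10^5$
  per age band, the textbook model for incidence counts.
* **Trend series** are piecewise log-linear with slope
  $\ln(1 + \mathrm{APC}/100)$ per segment, continuous at break years
  (matching the segmented-fit convention), with Gaussian noise on the
  log scale.
* **Seeding.** A single master seed expands into deterministic per-stream
  sub-seeds (a small multiplicative hash of the stream label), so adding
  a new generator never perturbs existing streams and fixed seeds give
  bit-identical outputs.

Default benchmark conditions mirror the study geometry: 62 counties,
candidate pools of 20–31 variables, planted standardized effects of 0.5,
outcome noise calibrated to a population $R^2$ of 0.5, 19-year trend
series (2000–2018) with log-scale noise SD 0.02 and 0–2 breakpoints.

## Problem sizes used in tests and the acceptance script

Oracle-equivalence suites run 100 random best-subset instances
($p \le 8$ candidates), 25–30 random conflict graphs ($p \le 12$),
40 randomized model pools, and 10–12 joinpoint series of 19 years.
Recovery benchmarks use 100 seeds for the planted-effect and planted-null
frames (n = 62, 20 candidates) and 200 series for APC coverage; these
sizes give Monte-Carlo standard errors comfortably inside the asserted
margins (e.g. a ≥ 80% hit-rate floor tested at an observed rate near
100%). The full suite and the acceptance script each complete in minutes
on a single core.

## Known limitations

* Ecological associations only; no individual-level inference.
* Model-selection inference is not corrected for selection.
* No spatial error structure; latitude terms capture smooth north–south
  gradients only.
* The permutation test for the number of joinpoints is approximate
  (conditional on the selected placement grid) and its p-values are
  granular at $1/(B+1)$.
* The inclusion filter and rate code assume counts aggregated to the
  standard bands supplied; no delay adjustment or within-county rate CIs
  are computed (the across-county SD is the dispersion the study design
  uses).
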