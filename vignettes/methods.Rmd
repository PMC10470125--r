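---
title: "Exposure-mixture inference for gestational metals and cerebral palsy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposure-mixture inference for gestational metals and cerebral palsy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmetals)
```

# The scientific problem

Cerebral palsy (CP) is the most common motor disability of childhood, with
a prevalence around 0.2%, and the aetiology of most congenital cases is
unknown. One candidate class of perinatal risk factors is gestational
exposure to toxic metals (As, Cd, Cs, Pb, Hg) and imbalances of essential
elements (Co, Cu, Mg, Mn, Se, Zn), all measurable in maternal blood during
pregnancy. Because people are exposed to these agents jointly, single-metal
regressions are both statistically unstable (the exposures are correlated)
and scientifically incomplete (effects may be joint, antagonistic, or
modified by covariates such as child sex and maternal education).

`cpmetals` implements, as a tested pipeline, the mixture-analysis strategy
used in nested case-control studies of this question:

1. **batch normalization** of concentrations measured in separate
   analytical rounds, using quality-control (QC) reference samples;
2. **winsorization** and natural-log transformation;
3. **bounded multiple imputation** of left-censored (below LOD/LOQ) and
   structurally missing values;
4. **elastic-net stability selection** with permutation p-values to rank
   exposures (and two-way interactions) by their association with CP;
5. **pooled logistic effect models** (OR per interquartile-range increase),
   natural-spline checks of linearity, interaction visualization, and a
   sensitivity-analysis suite;
6. **quantile g-computation** of the joint effect of three mixtures
   (all 11 metals; the 5 toxic metals; the 6 essential elements).

Registry-linked cohort data of this kind are access-restricted, so the
package ships a calibrated synthetic cohort generator and every stage is
exercised end to end on simulated data with known ground truth. The
generator's defaults encode the study conditions: 144 cases and 1,082
controls drawn from a large pregnancy cohort.

# The synthetic cohort generator

## Exposure marginals

Each metal's concentration is log-normal, calibrated by the method of
moments to the published arithmetic mean and SD of the study sample
(e.g. Hg 1.4 (0.9) µg/L, Cu 1,588 (248) µg/L, Mn 11.5 (9.4) µg/L; Mg in
mg/L). Given a mean $m > 0$ and SD $s$, the ln-scale parameters are

$$\sigma^2 = \ln\!\left(1 + (s/m)^2\right), \qquad
  \mu = \ln m - \sigma^2/2 .$$

Moment calibration was chosen over quantile calibration because the mean
and SD are the most complete published summary for all eleven analytes.
A consequence worth stating plainly: the generator reproduces means, SDs
and rank correlations, but **not** the published medians or extreme
percentiles of the real data, which is not exactly log-normal. Tests
therefore never assert on simulated medians.

## Dependence

Dependence is a Gaussian copula. A target Spearman correlation
$\rho_s$ for a pair of metals is converted to the latent Pearson
correlation $\rho_p = 2\sin(\pi\rho_s/6)$, which makes the simulated
ranks reproduce the target. The two strongest published pairs ship as
defaults (As–Hg 0.59, Mg–Zn 0.53); unlisted pairs default to zero. If a
user-supplied correlation set implies a non-positive-definite latent
matrix it is repaired to the nearest PSD correlation matrix with a
warning.

## Covariates and outcome

Covariates are drawn independently, matched to the published sample
margins (maternal age 30.1 (4.5) years; seafood intake 36.2 (21.8) g/day;
folate 515.5 (273.1) µg/day; gestational age 277.9 (16.0) days; BMI 23.5
(6.1); parity 56% parous; 66.1% with ≥5 years of university education;
12.8% smoking; 32.5% girls; 24% born 2006 or later). Skewed non-negative
covariates (seafood, folate, BMI) use moment-matched log-normals; the
rest are normal or Bernoulli. Only margins are published, so no
covariate–covariate dependence is modeled unless supplied.

Case status follows a logistic model on the source population whose
default intercept gives a 2% source prevalence and whose default
coefficients are all zero (the global null). Metal coefficients are
expressed per 1 SD of the ln-scale concentration so that effect sizes are
comparable across analytes. The nested case-control design is mimicked
directly: a source population (default 100,000) is simulated and exactly
144 cases and 1,082 controls are drawn, rather than reproducing cohort
prevalence.

## Batch structure, censoring and missingness

Subjects are assigned to three analytical rounds with proportions
(0.40, 0.35, 0.25); each metal in round $k$ is multiplied by a bias
(defaults 1.0, 1.1, 0.9 — arbitrary but documented, and overridable) and
by per-sample log-normal measurement noise with 2% CV. Each round also
yields five QC replicates of a per-metal reference value with 5% CV. The
noise multipliers are mean-one log-normals, so the batch bias is the only
systematic distortion.

Left-censoring is applied on the raw (measured) scale: As below its LOD
and Cd/Co below their LOQs become missing with machine-readable reasons.
The limits are not published (they live in an inaccessible supplement),
so the shipped defaults are calibrated as the marginal quantiles that
reproduce the published below-limit counts (12, 22 and 33 of 1,226). A
fraction 105/1226 of subjects form an external-laboratory subset in which
Mg and Cs were not analysed; covariate missingness is MCAR at the
published missing rates (e.g. folate 273/1226). Mg is summarized in the
source study for controls only; the generator treats it like every other
metal, as the more useful convention for testing.

# Preprocessing

Batch adjustment multiplies each measured value by the ratio of the
pooled geometric mean of that metal's QC replicates (across all rounds)
to the geometric mean within the sample's own round:
$M^*_{ij} = M_{ij} \times \overline{QC}_{l} / \overline{QC}_{lk}$.
"Pooled across rounds" means the geometric mean of all replicates, not
the mean of round means — the two differ with unbalanced replicates and
the former matches the stated definition.

Winsorization replaces values below the 1st and above the 99th pooled
percentile of each metal with those percentile values; the percentile
rule throughout the package is linear interpolation between closest
ranks (R type 7), fixed and documented because the source description
names no rule. The order of operations is batch adjustment, then
winsorization, then ln transform: the ratio adjustment is defined for
raw concentrations, while winsorization is described on analysis values.
Whether the original analysis winsorized before or after adjustment is
not stated; the chosen order is a design decision of this package, and
the no-winsorization variant is available as a sensitivity scenario.
Winsorizing and taking logs commute exactly for interior values; the two
caps differ at second order because percentile interpolation is linear
on the working scale.

ORs are reported per interquartile-range increase in the ln-scale
exposure, so `preprocess()` records each metal's ln-scale IQR under the
same percentile rule. Units are preserved (Mg stays in mg/L): every
downstream analysis is scale-equivariant after the ln transform and
standardization, so no unit harmonization is needed.

# Multiple imputation

The imputation model is a multivariate normal over case status, the 11
ln-scale metals, the adjustment covariates, and three auxiliary
variables (gestational age, folate, BMI), with binary variables coded
0/1. Estimation uses EM with rows grouped by missingness pattern; the
observed-data log-likelihood is monitored and must not decrease
(tolerance `1e-6` relative, cap 500 iterations — neither is published,
both are configurable).

Imputation is bootstrap-EM: for each of $M$ imputations the rows are
resampled, EM is fitted on the resample, and missing cells of the
original table are drawn from their conditional normal given the row's
observed cells. This propagates parameter uncertainty without requiring
posterior draws. Left-censored cells carry bounds: on the ln scale,
lower $\ln(L/10)$ and upper $\ln(L)$, where $L$ is the LOD (As) or LOQ
(Cd, Co) carried through the round's batch-adjustment factor. The
lower bound stands in for "approximately zero" while keeping the support
strictly positive; the factor 1/10 is a documented, configurable choice.
Bounded cells are drawn by joint rejection with a retry cap and fall
back to truncated univariate Gibbs updates, so bounds hold in every
dataset by construction. Binary cells are drawn continuous and
thresholded at 0.5 — a documented simplification of the MVN model. Case
status is always a predictor and is never imputed (it is fixed by
design in a case-control sample).

Scalar estimates are pooled by Rubin's rules
($T = W + (1 + 1/M)B$, Barnard–Rubin degrees of freedom), and
likelihood-ratio statistics by the D2 rule (pooled chi-square from the
mean statistic with a between-imputation correction); the source
publication does not state how spline LR tests were pooled, so D2 is
this package's documented choice.

# Stability selection

The design matrix holds the 11 standardized ln-scale metals (penalized)
and the 7 adjustment covariates — child sex, birth-year period, parity,
maternal education, smoking, maternal age, seafood intake — which are
never penalized. The interaction design adds all 55 metal×metal and 22
metal×{sex, education} products of standardized parents (products are
not re-standardized). The elastic net uses mixing parameter
$\alpha = 0.9$ (published for the interaction run; adopted for both) and
chooses lambda per fit by k-fold cross-validated deviance at the
deviance-minimizing value. The CV loop is implemented directly around
`glmnet` for speed; the rule is identical to `cv.glmnet`'s
`lambda.min`. Inside bootstrap resamples the CV folds are grouped by
original subject, so duplicated rows never sit on both sides of a fold
boundary: ungrouped folds let the held-out deviance reward overfitting
to duplicates, bias lambda low, and inflate the null selection rate
(about 0.30 per term versus 0.09 with grouping in the package's own
measurements at n = 1,226).

Stability selection resamples cases and controls with replacement
separately (preserving the case count), imputes each resample $M$ times,
runs the elastic net per imputed dataset, and averages: the per-resample
selection frequency is the fraction of the $M$ datasets selecting the
term, and $P_{sel}$ is its mean over the $B$ resamples. When the input
table is complete the $M$ imputed copies coincide and one fit per
resample suffices; the implementation detects this.

Permutation p-values permute the case labels against the entire design
(breaking the exposure–outcome and covariate–outcome links jointly,
which is valid under the global null being tested), rerun a reduced
stability selection per permutation, and count:
$p = (1 + \#\{P_{sel}^{null} \ge P_{sel}^{obs}\})/(1 + K)$. Exposures
with $p \le 0.05$ and $P_{sel} > 0.6$ are carried to the effect models
($p \le 0.1$ for the interaction run); Benjamini–Hochberg step-up
thresholds at $\alpha = 0.05$ (0.1 for interactions) provide the
multiplicity assessment.

A property of this construction worth knowing: $P_{sel}$ is an average
of $B \times M$ selection indicators, so at small resampling depth it is
a coarse lattice statistic, the permutation p-value inherits heavy ties,
and its null distribution is conservative and lumpy rather than
uniform. Approximate uniformity emerges only as the resampling depth of
the observed and null runs grows (and requires the two depths to match,
since the counting comparison assumes exchangeability). Simulation
studies using this package at desk scale should therefore treat the
permutation p-values as valid but conservative, not as exactly uniform.
The published run accounting (its text and figure captions disagree on
the resample, imputation and permutation counts) is exposed as
configuration: `pipeline_config("paper")` uses B = 200, M = 20,
K = 1,200 with reduced null runs of 20 × 10, and
`pipeline_config("reduced")` is the desk-scale profile.

# Effect models

Selected exposures enter multivariable adjusted logistic models, one per
imputed dataset, pooled by Rubin's rules; both single-exposure and
co-adjusted (all selected exposures together) variants are reported as
OR per ln-scale IQR, $\exp(\beta \cdot IQR)$, with both factors on the
ln-concentration scale (the reporting scale is not published; this is
the package's choice).

Nonlinearity is checked by a likelihood-ratio test of the linear term
against a natural cubic spline with knots at the 10th, 50th and 90th
percentiles of the pooled ln exposure — implemented as one internal knot
at the median with boundary knots at the outer two (an alternative with
all three internal is available). LR statistics are pooled by D2.

Selected interactions are fitted jointly (with their standardized main
effects and the covariates) and exported as predicted log-odds curves of
each metal at ±1 SD of its partner, the plot-ready form of the published
line graphs. The sensitivity suite re-estimates the co-adjusted models
restricted to term births (gestational age ≥ 259 days, the stated
37-week threshold), non-SGA children (SGA taken as an input flag),
non-smoking mothers, the no-winsorization variant, complete cases
(no imputation), and folate strata split at the per-dataset median of
imputed folate intake.

# Quantile g-computation

Members of a mixture (MixAll: all 11; MixTox: As, Hg, Cd, Cs, Pb;
MixEssential: Mn, Cu, Co, Se, Mg, Zn) are scored into quartiles (the
same percentile rule; cut-points computed per imputed dataset and
logged). The core estimator fits a logistic model of the outcome on all
member scores plus covariates; the joint effect $\psi$ of raising every
member by one quantile is the sum of the member coefficients, with
variance the full member block of the coefficient covariance — the
cross-covariances matter because quantized members remain correlated.
$\psi$ is pooled across imputations and reported as an OR per quantile.
Member weights are computed from the imputation-averaged coefficients
and partitioned by sign, each partition normalized to sum to 1 (how MI
and weights interact is unspecified in the source; averaging before
partitioning is this package's choice).

The bootstrap variant fits the conditional model with optional
per-member quadratic terms and supplied interaction terms, then
g-computes the marginal effect: the population-averaged log-odds is
evaluated at each counterfactual joint setting $s = 0, \dots, q-1$ and a
polynomial in $s$ is fitted to the grid by least squares; $\psi$ is the
linear coefficient, with subject-level bootstrap CIs pooled across
imputations. Averaging the linear predictor (log-odds) rather than
probabilities makes the degree-1, no-interaction case collapse exactly
onto the core estimator — a closed-form identity the tests assert at
`1e-6`. Leave-one-out re-estimation (e.g. MixTox without Hg) uses the
core estimator on the reduced member set.

# Numerical choices and degenerate inputs

* Percentiles: linear interpolation between closest ranks everywhere
  (winsorization, IQR, spline knots, quantile cut-points).
* Quantization requires at least `q` distinct values and distinct
  cut-points; constant vectors are errors naming the metal.
* EM ridge-stabilizes a numerically singular covariance with a warning;
  non-convergence is an error carrying the likelihood trace.
* Collinear quantized members are ridge-stabilized with a warning;
  rank-deficient interaction models drop aliased terms with a warning.
* Stratified resamples with fewer than 5 cases are redrawn; bootstrap
  resamples with no cases are redrawn and counted.
* All stochastic stages are pure functions of (data, config, seed); a
  master seed expands deterministically into per-stage sub-seeds.

# Problem sizes used by the shipped checks

The package's simulation checks run at the study's sample size
(n = 1,226) where the claim concerns that design, and at smaller sizes
where the claim is generic: generator calibration uses n = 100,000
draws; the stability-selection discrimination study uses 50 replicates
of n = 1,226 with B = 50 resamples and K = 99 permutations on complete
exposure data (where the imputed copies coincide); null-calibration
studies use 200 replicates at n = 150–200 with symmetric observed/null
resampling depth; spline size checks use 1,000 outcome redraws on a
fixed design; mixture coverage uses 100 outcome redraws at n = 1,226.
These sizes are the package's documented simulation design.

# Known limitations

* The generator reproduces means, SDs and rank correlations, not the
  real data's full shape: no skew beyond log-normal, no covariate
  dependence, no informative missingness. Passing tests demonstrate
  correctness of the machinery under these conditions, not
  reproduction of the real-data estimates, which require restricted
  registry data.
* Permutation p-values at small resampling depth are conservative (see
  above); BH assessment of them is correspondingly conservative.
* The MVN imputation model is misspecified for binary variables
  (threshold draw) and for heavy-tailed metals; this mirrors the
  standard practice it emulates.
* The elastic-net mixing parameter is fixed at 0.9 rather than tuned;
  lambda is tuned per fit, so selection probabilities mix over CV
  randomness as intended by stability selection.
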