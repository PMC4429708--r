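---
title: "Methods: level and variability of ART adherence and their impact on outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: level and variability of ART adherence and their impact on outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In long-running HIV antiretroviral-therapy (ART) cohorts, monthly pill-count
adherence is strongly predictive of virological suppression, immune recovery
and survival. Most analyses summarise adherence by its *level* (an average
over some window). This package implements an analysis that separates the
level from the *variability* of adherence over time and quantifies the
effect of each on three outcomes: the probability of an undetectable viral
load, the monthly change in CD4 cell count, and mortality.

The pipeline has four statistical stages, each exposed as ordinary R
functions and exercised end-to-end on a synthetic cohort generator with
known ground truth.

## Moving statistics and the standardized variance

From month 12 onward, each patient-month receives the mean and the sample
variance (denominator $n-1$) of the previous twelve monthly adherence
percentages (`moving_mean_variance()`). A window is used only when all 12
months are observed; the statistic would otherwise mix window sizes and
change meaning across patient-months. A `min_months` switch relaxes this to
a $\ge k$-of-12 rule when sparser data demand it.

The moving variance is strongly negatively linked with the moving mean
(near-perfect adherence leaves little room to vary), so the raw variance
mostly repeats the information in the mean. `standardize_variances()`
removes this dependence non-parametrically:

1. pool all patient-months, sort by moving mean (stable on ties);
2. partition into $K = \max(1, \mathrm{round}(N/30))$ consecutive
   small-amplitude bins of near-equal size (remainder spread one per bin
   from the first bin — for any $N$ this reproduces bins of "nearly 30");
3. within a bin of size $n_c$, the variance with rank $k$ (average ranks on
   ties) is mapped to $z = \Phi^{-1}\!\big(k/(1+n_c)\big)$.

The result is a variance measure with the same within-bin distribution at
every mean level, hence decorrelated from the mean by construction: on a
pooled synthetic cohort of ~14,500 patient-months the absolute Spearman
correlation is below $10^{-3}$ (the raw quantities correlate at about
$-0.9$). Its range is bounded by $\pm\Phi^{-1}(n_{\max}/(1+n_{\max}))$,
which is $\pm 1.85$ for bins of 30 — so with near-equal bins the full
theoretical range is attained as soon as some bin is monotone in variance.
The fitted binning is returned as a map (`apply_std_map()`) so held-out
patient-months can be standardized against a training pool; a new point
joins the bin whose mean interval contains it, or the nearest boundary bin.
Alternative de-trendings (regression residuals, coefficients of variation)
are deliberately not implemented: the rank-normal transform makes no
functional-form assumption about the mean-variance link.

## The latent-class trajectory model

Typical adherence trajectories are modelled by a 3-class finite mixture of
linear mixed models (`fit_lcmm()`). Conditionally on patient $i$ belonging
to class $j$, the longitudinal vector $y_i$ is Gaussian with mean
$X_i\beta_j$ and covariance $V_i = Z_i D Z_i^\top + \sigma^2 I$, where
$Z_i = [1, t]$ carries a random intercept and a random slope on time with
free correlation. The marginal criterion is

$$\ell = \sum_i \log \sum_j \pi_j\,\varphi(y_i;\, X_i\beta_j,\, V_i).$$

**Time basis.** The class curves live on a linear-spline (hinge) basis
$[1, t, (t-12)_+, (t-24)_+, \ldots, (t-96)_+]$ with knots every 12 months
(`basis_config()`, `design_row()`). A hinge basis with yearly knots is the
minimal form that allows a curve to change slope several times over nine
years while staying linear in the coefficients; the basis is pluggable
should a different form be preferred. Because observations start at month
12, the first hinge $(t-12)_+ = t-12$ is exactly collinear with the
intercept and linear columns; `fit_lcmm()` detects aliased columns by
pivoted QR, fixes their coefficients at 0 and reports them in `$aliased` —
fitted curves are unaffected.

**Estimation.** EM with a closed-form E-step
($p_{ij} \propto \pi_j \varphi_{ij}$, computed with log-sum-exp guarding)
and an M-step that updates $\pi$ in closed form, profiles each $\beta_j$ by
weighted generalized least squares at any candidate variance parameters,
and improves $(D, \sigma)$ by a short Nelder-Mead run on a
$(\log s_0, \log s_1, \operatorname{atanh}\rho, \log\sigma)$ scale started
from the current values. Because each M-step never decreases the expected
complete-data criterion, the observed log-likelihood is non-decreasing
(generalized EM); this is asserted by the tests on every run. After
convergence (relative log-likelihood change below `tol`, default $10^{-6}$,
up to `max_iter` = 500) the variance parameters are polished by long
Nelder-Mead and BFGS runs, which for one class makes the fit a plain
maximum-likelihood mixed-model fit — it matches a tightly converged
`lme4::lmer` ML fit to about $10^{-6}$ on all parameters.

Numerical choices: per-patient covariance factorizations are shared across
patients with identical observation times; $\sigma$ is floored at $10^{-4}$
to prevent degenerate spikes; $D$ and $\sigma$ are shared across classes
(with three classes and small classes, class-specific covariances
destabilise EM; the shared form identifies the class structure through the
mean curves, which is what the classification uses). Initialization is
k-means on ridge-regularized per-patient OLS coefficients of the same
basis, perturbed across `n_starts` seeded restarts; the best final
likelihood wins. Ties in the MAP rule (`map_classify()`) break towards the
lowest class index.

Classes are relabelled for reporting (`relabel_classes()`): mean
trajectories by decreasing level at month 12 (class 1 = constantly high),
variability trajectories by increasing level (class 1 = low). The same
fitting routine is applied unchanged to the standardized-variance series.
The number of classes is fixed at three by design; model selection over $J$
is out of scope.

## Outcome-association stages

**Undetectable viral load.** Each laboratory visit at month $m$ belongs to
six-month period $\lceil m/6 \rceil$; the therapy-initiation baseline
(month 0) is excluded, where undetectable viral load is near-absent. The
indicator of viral load strictly below 1000 copies/mL is modelled by a
mixed logistic regression on the full mean-class by variance-class
interaction with a random intercept on the *period* (the calendar-period
reading of a "six-month" random effect; a patient-level intercept is a
possible alternative reading, noted but not implemented). The reference
cell is DrI mean adherence with High variability, so the main effects are
the published contrasts. With a single period the model degenerates to
ordinary logistic regression, which the function detects and reports.

**CD4 change.** The six-month CD4 change divided by 6 (cells/mm³/month)
gets the same fixed-effect structure and random intercept. The period-1
change may use the baseline CD4 as its previous value: the baseline
exclusion concerns the near-zero baseline *undetectable percentages*, not
the CD4 measurement itself.

**Mortality.** Follow-up is expanded into monthly counting-process episodes
$(m, m+1]$ carrying that month's moving mean (scaled per 10 adherence
points) and standardized variance, with late entry at month 12 — moving
covariates do not exist earlier, so the first year contributes no risk
time; this is a documented divergence risk versus analyses that start the
risk set at therapy initiation. Cox models (`survival::coxph`) use the
Efron tie approximation by default (ties are dense on a monthly grid;
Breslow available by flag), in univariate and multivariate modes with an
optional mean-by-variance interaction. Missing covariate months are carried
forward from the last available moving point.

## The synthetic cohort generator

`generate_cohort()` produces cohorts with exactly the latent structure the
analysis assumes, so every stage can be tested by parameter recovery. Its
defaults emulate a 317-patient West African ART cohort followed 108 months:

* **Mean classes** (piecewise-linear control points, shares 221/54/42 out
  of 317): constantly high at 95%; high-but-slowly-decreasing 90% to month
  48 declining to 65% by month 84 and rising to ~85% in the final year; and
  decreasing-then-rapidly-increasing 80% in year one, 48% at month 36,
  recovering to 90% by month 84. The terminal rise of the second class is
  *not* hard-coded as a survivor effect: it is the curve the survivors of
  that class would show, and the hazard model reproduces the selection
  implicitly.
* **Variability strata** (shares 71/155/91): monthly noise SDs of 3, 7 and
  12 adherence points. No within-class noise levels are published for the
  emulated cohort; these are calibration choices that produce standardized
  variance strata of clearly separated levels while keeping the mean
  classes recoverable. Noise is added and then truncated to $[0,100]$
  (adherence is a pill-count proportion); near the 100% boundary the
  truncation pulls realized means a point or two below the nominal curve,
  which the tests account for by checking curve recovery away from the
  boundary.
* **Laboratory visits** every 6 months: CD4 is a Gaussian baseline
  (mean 230, SD 100 cells/mm³, consistent with enrolment under a <350
  criterion) plus a class-specific linear trend (4.74/4.32/0.04
  cells/mm³/month, so the cH-DrI and HsD-DrI differences are 4.70 and 4.28)
  plus measurement noise (SD 30). The undetectable-VL indicator follows
  cell log-odds calibrated to the published odds ratios (cH vs DrI 2.91,
  HsD vs DrI 2.88, with the within-class variance contrasts), a shared
  period random effect (SD 0.25), and a near-zero success probability at
  baseline; a viral-load value consistent with the indicator is drawn
  log-uniformly on the corresponding side of 1000 copies/mL.
* **Mortality**: a discrete monthly hazard from month 12,
  $\lambda_m = \lambda_0 \exp(\log(0.73)\, \bar y_m/10 + \log(1.45)\, z_m)$,
  driven by the patient's own moving mean and *population*-standardized
  variance (computed through the package's own moving-statistics stage
  before death is drawn). $\lambda_0 = 0.026$ is calibrated so the overall
  death fraction is near 16%. The hazard-ratio defaults are the published
  multivariate values; the published univariate standardized-variance HR
  (1.49) differs slightly and is not a generator parameter. Survival is
  simulated on the monthly grid because the covariates update monthly;
  a continuous-time refinement is out of scope.

All randomness flows from one seed through splittable L'Ecuyer-CMRG
streams, one per patient plus one cohort-level stream: appending patients
leaves earlier patients' draws untouched, and death uniforms are coupled
across configurations sharing a seed (used by the hazard monotonicity
test). Measurements are rounded at creation (adherence to 2 decimals, CD4
to 1, viral load to integers), so the CSV round trip is exact and repeated
writes are byte-identical.

What the generator does *not* emulate: dropout and intermittent missed
visits (censoring is administrative or by death only), drug-specific
adherence, correlation between a patient's adherence level and the noise
scale beyond truncation, secular calendar-time trends, and measurement
error in the pill counts themselves. Passing recovery tests therefore show
that the estimators recover the data-generating parameters under the
model's own assumptions — not that those assumptions hold in any real
cohort.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulations use cohorts of 150-400
patients (standardization properties on ~14,500 pooled patient-months;
latent-class recovery on 300 patients with noise SDs 3/3.5/4, where MAP
agreement is required to reach 95%; outcome-model recovery as a
20-replicate ensemble of 250-400 patients whose 95% band must cover the
generating values) and one 1,500-2,000-patient null cohort with an elevated
baseline hazard so the null hazard-ratio check has ample events. These
sizes were chosen to keep Monte-Carlo error well below the effect sizes
being recovered. `scripts/acceptance.R` re-runs all of it from a single
`--seed` and writes the resulting quantities as JSON.

## Known limitations

* The hinge time basis is a reconstruction choice; any basis expressible as
  fixed columns over time can be substituted via `basis_config()`, but knot
  placement is not data-driven.
* Shared $D, \sigma$ across classes can misattribute genuinely
  class-specific volatility to the class curves.
* The standardization's bin boundaries depend on the pooled sample; two
  pools with different mean distributions give different maps. Whether
  patient-months should be pooled across patients at all is a judgement
  call — pooling is used here, and the map object makes the choice
  explicit and reusable.
* With heavy tied adherence values, bin membership of tied means follows
  the stable sort order; a different (unknowable) tie placement could move
  individual points one bin over.
* The Cox stage's late entry at month 12 discards first-year deaths; in
  cohorts with substantial early mortality the estimates condition on
  surviving the first year.
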