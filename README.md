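# adheretraj

Level *and* variability of adherence to HIV antiretroviral therapy (ART),
and their impact on the immunovirological response and mortality.

Longitudinal ART cohorts usually summarise pill-count adherence by its
average. This package implements the complementary analysis for
biostatisticians working with such cohorts: it separates the *level* of
adherence from its *variability* over time and quantifies the effect of
each on undetectable viral load, CD4 recovery and death.

The analysis core is:

* **Moving statistics** — from month 12, each patient-month gets the mean
  and sample variance of the previous 12 monthly adherence values.
* **Standardized variance** — moving means are pooled, sorted and cut into
  bins of ~30; within a bin of size `n`, the variance of rank `k` maps to
  `z = Φ⁻¹(k / (1 + n))`. This rank-normal transform yields a variability
  measure decorrelated from the mean (|Spearman ρ| < 0.001 on pooled
  synthetic data) and bounded by ±Φ⁻¹(30/31) ≈ ±1.85 for bins of 30.
* **Latent-class trajectories** — a 3-class mixture of linear mixed models
  on a hinge-spline time basis `[1, t, (t−12)₊, …, (t−96)₊]`, random
  intercept + slope, fitted by (generalized) EM with multi-start; patients
  are classified by the maximum a posteriori (MAP) rule. Applied to the
  moving means (classes *cH* constantly-high, *HsD* high-slowly-decreasing,
  *DrI* decreasing-then-rapidly-increasing) and, unchanged, to the
  standardized variances (Low / Moderate / High variability).
* **Outcome models** — mixed logistic regression for undetectable viral
  load (< 1000 copies/mL) and a mixed linear model for monthly CD4 change
  (both on the full class interaction, random intercept on the six-month
  period, reference cell DrI × High), and a time-dependent Cox model on
  monthly counting-process episodes carrying the moving mean (per 10
  points) and the standardized variance.
* **Synthetic cohort generator** — cohorts with this exact latent
  structure and published effect sizes as defaults (undetectable-VL odds
  ratio 2.91 for cH vs DrI, CD4 slope difference 4.70 cells/mm³/month,
  death hazard ratios 0.73 per 10 adherence points and 1.45 per unit of
  standardized variance), used as ground truth by the recovery tests.

See `vignettes/adherence-variability-methods.Rmd` for the model details,
calibration choices and limitations.

## Worked example

```r
library(adheretraj)

cfg <- cohort_config(n_patients = 150, seed = 2718)
co  <- generate_cohort(cfg)
co
#> Synthetic ART cohort: 150 patients, 15187 adherence records, 2674 visits
#>   deaths: 20 (13.3%), follow-up censored at 108 months

mv  <- moving_mean_variance(co$adherence)     # 12-month moving stats
std <- standardize_variances(mv)              # rank-normal standardization
std$map
#> Variance standardization map: 451 classes (target size 30)
#>   class sizes 30-31; mean range [42.29, 99.43]

ep  <- build_survival_episodes(std$points, co$survival)
fit_cox_td(ep, terms = "both")
#>                term estimate ratio ci_low ci_high level    model
#> 1 moving_mean_per10   -0.329  0.72  0.524   0.989  0.95 cox_both
#> 2      std_variance    0.349  1.42  0.873   2.305  0.95 cox_both
```

Each 10-point rise in the 12-month moving mean multiplies the death hazard
by 0.72 (28% lower risk), and each unit of standardized variance multiplies
it by 1.42 — with 150 patients the generating values 0.73 and 1.45 are
recovered within the confidence intervals. The same cohort's
undetectable-VL stage (using the generator's true classes):

```r
classes <- with(co$truth, data.frame(patient_id, mean_class = true_mean_class,
                                     var_class = true_var_class))
outc <- build_six_month_outcomes(co$visits, classes)
fit_mixed_logistic(outc)[2:3, ]
#>            term estimate ratio ci_low ci_high level          model
#> 2 mean_classHsD     1.55  4.69   2.15   10.24  0.95 mixed_logistic
#> 3  mean_classcH     1.06  2.90   1.64    5.13  0.95 mixed_logistic
```

The cH-vs-DrI odds ratio of an undetectable viral load is estimated at
2.90 against a generating value of 2.91.

For an end-to-end run (simulate → moving → trajectories → outcomes →
report, with a hashed output manifest):

```r
cfg <- pipeline_config(outdir = "run1", seed = 1)
run_pipeline(cfg)
```

or from a shell via the thin wrapper
`inst/scripts/adherence-pipeline.R all --outdir run1 --seed 1`.

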