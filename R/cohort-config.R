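#' Default mean-adherence trajectory archetypes
#'
#' Piecewise-linear control points (month, adherence %) for the three
#' archetypal mean-adherence trajectories seen in long-running ART cohorts:
#' \describe{
#'   \item{cH}{constantly high, close to 95\% throughout;}
#'   \item{HsD}{high but slowly decreasing, about 90\% up to month 48,
#'     declining to about 65\% by month 84, then rising towards 85\% over the
#'     final year (a survivor-selection artefact the hazard model reproduces
#'     implicitly);}
#'   \item{DrI}{decreasing then rapidly increasing, about 80\% in the first
#'     year, falling below 50\% around month 36, recovering to about 90\% by
#'     month 84.}
#' }
#' Values between control points are linearly interpolated.
#'
#' @return named list of two-column matrices (`month`, `adherence`).
#' @export
default_mean_curves <- function() {
  list(
    cH  = cbind(month = c(0, 108), adherence = c(95, 95)),
    HsD = cbind(month = c(0, 48, 84, 96, 108), adherence = c(90, 90, 65, 65, 85)),
    DrI = cbind(month = c(0, 12, 36, 84, 108), adherence = c(80, 80, 48, 90, 90))
  )
}

#' Cell log-odds of undetectable viral load for the synthetic cohort
#'
#' Builds the 3 x 3 matrix of log-odds of an undetectable viral load
#' (< 1000 copies/mL) for each mean-class x variance-class cell, from an
#' intercept (the DrI x High reference cell), log odds-ratios for the mean
#' classes (at High variance) and within-mean-class log odds-ratios for
#' Low/Moderate versus High variance. Defaults are calibrated so that the
#' cH-vs-DrI odds ratio is 2.91 and the HsD-vs-DrI odds ratio is 2.88, with
#' the within-class variance contrasts 1.82/1.76 (cH), 1.71/0.69 (HsD) and
#' 1.73/1.28 (DrI).
#'
#' @param intercept log-odds in the DrI x High reference cell.
#' @param mean_or odds ratios for `c(cH, HsD)` versus DrI.
#' @param var_or 3 x 2 matrix of within-mean-class odds ratios, rows
#'   `cH, HsD, DrI`, columns `Low, Moderate` (versus High).
#' @return 3 x 3 matrix of log-odds, rows `cH, HsD, DrI`, columns
#'   `Low, Moderate, High`.
#' @export
vl_logit_cells <- function(intercept = 0.4,
                           mean_or = c(cH = 2.91, HsD = 2.88),
                           var_or = rbind(
                             cH  = c(Low = 1.82, Moderate = 1.76),
                             HsD = c(Low = 1.71, Moderate = 0.69),
                             DrI = c(Low = 1.73, Moderate = 1.28))) {
  mean_lo <- c(cH = log(mean_or[["cH"]]), HsD = log(mean_or[["HsD"]]), DrI = 0)
  cells <- matrix(NA_real_, 3, 3,
                  dimnames = list(c("cH", "HsD", "DrI"),
                                  c("Low", "Moderate", "High")))
  for (m in rownames(cells)) {
    cells[m, "High"] <- intercept + mean_lo[[m]]
    cells[m, "Low"] <- cells[m, "High"] + log(var_or[m, "Low"])
    cells[m, "Moderate"] <- cells[m, "High"] + log(var_or[m, "Moderate"])
  }
  cells
}

#' Configuration for the synthetic adherence cohort generator
#'
#' Defines the latent structure of a simulated ART cohort: three
#' mean-adherence trajectory archetypes, three adherence-variability strata
#' (class-specific noise SDs), six-monthly CD4/viral-load visits whose
#' distributions depend on the latent classes, and a monthly discrete death
#' hazard that is log-linear in the current 12-month moving mean and the
#' population-standardized moving variance of adherence.
#'
#' Defaults emulate a West African ART cohort followed for 9 years: 317
#' patients, class shares (221, 54, 42)/317 for cH/HsD/DrI and
#' (71, 155, 91)/317 for Low/Moderate/High variability, hazard ratios 0.73
#' per 10 adherence points of moving mean and 1.45 per unit of standardized
#' variance, and an overall death fraction near 16\%. Noise SDs, the CD4
#' parameters and `hazard_base` are calibration choices documented in the
#' package vignette.
#'
#' @param n_patients number of patients.
#' @param max_month administrative censoring time in months (> 12).
#' @param mean_class_probs probabilities of the cH/HsD/DrI mean classes
#'   (must sum to 1).
#' @param var_class_probs probabilities of the Low/Moderate/High variability
#'   strata (must sum to 1).
#' @param mean_curves list of piecewise-linear control-point matrices, as
#'   [default_mean_curves()].
#' @param noise_sd_by_var_class strictly increasing monthly adherence noise
#'   SDs (percentage points) for Low/Moderate/High variability.
#' @param visit_interval months between laboratory visits.
#' @param cd4_baseline_mean,cd4_baseline_sd baseline CD4 distribution
#'   (cells/mm3).
#' @param cd4_slope_by_class true CD4 slope (cells/mm3/month) per mean class
#'   `c(cH, HsD, DrI)`; defaults reproduce slope differences of 4.70 (cH -
#'   DrI) and 4.28 (HsD - DrI).
#' @param cd4_visit_sd measurement SD of a CD4 visit (cells/mm3).
#' @param vl_logit 3 x 3 matrix of cell log-odds of undetectable viral load,
#'   see [vl_logit_cells()].
#' @param vl_period_sd SD of the shared six-month-period random intercept on
#'   the undetectable-VL logit scale.
#' @param hazard_base baseline monthly death hazard (before covariate
#'   effects), active from month 12.
#' @param log_hr_mean_per_10pct log hazard ratio per 10 points of moving
#'   mean adherence (default `log(0.73)`).
#' @param log_hr_stdvar_per_unit log hazard ratio per unit of standardized
#'   moving variance (default `log(1.45)`).
#' @param seed integer seed; the generator is fully reproducible given the
#'   configuration and seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 317L,
                          max_month = 108L,
                          mean_class_probs = c(cH = 221, HsD = 54, DrI = 42) / 317,
                          var_class_probs = c(Low = 71, Moderate = 155, High = 91) / 317,
                          mean_curves = default_mean_curves(),
                          noise_sd_by_var_class = c(Low = 3, Moderate = 7, High = 12),
                          visit_interval = 6L,
                          cd4_baseline_mean = 230,
                          cd4_baseline_sd = 100,
                          cd4_slope_by_class = c(cH = 4.74, HsD = 4.32, DrI = 0.04),
                          cd4_visit_sd = 30,
                          vl_logit = vl_logit_cells(),
                          vl_period_sd = 0.25,
                          hazard_base = 0.026,
                          log_hr_mean_per_10pct = log(0.73),
                          log_hr_stdvar_per_unit = log(1.45),
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), max_month = as.integer(max_month),
    mean_class_probs = mean_class_probs, var_class_probs = var_class_probs,
    mean_curves = mean_curves,
    noise_sd_by_var_class = noise_sd_by_var_class,
    visit_interval = as.integer(visit_interval),
    cd4_baseline_mean = cd4_baseline_mean, cd4_baseline_sd = cd4_baseline_sd,
    cd4_slope_by_class = cd4_slope_by_class, cd4_visit_sd = cd4_visit_sd,
    vl_logit = vl_logit, vl_period_sd = vl_period_sd,
    hazard_base = hazard_base,
    log_hr_mean_per_10pct = log_hr_mean_per_10pct,
    log_hr_stdvar_per_unit = log_hr_stdvar_per_unit,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 0L) stop_cfg("n_patients must be non-negative")
  if (cfg$max_month <= 12L) stop_cfg("max_month must exceed 12")
  for (nm in c("mean_class_probs", "var_class_probs")) {
    p <- cfg[[nm]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop_cfg(nm, " must be 3 non-negative probabilities summing to 1")
  }
  sds <- cfg$noise_sd_by_var_class
  if (length(sds) != 3L || any(sds < 0))
    stop_cfg("noise_sd_by_var_class must be 3 non-negative SDs")
  if (!all(sds == 0) && !all(diff(sds) > 0))
    stop_cfg("noise_sd_by_var_class must be strictly increasing ",
             "(low < moderate < high) or all zero")
  for (nm in names(cfg$mean_curves)) {
    cm <- cfg$mean_curves[[nm]]
    if (any(cm[, "adherence"] < 0 | cm[, "adherence"] > 100))
      stop_cfg("mean curve '", nm, "' leaves [0, 100]")
    if (is.unsorted(cm[, "month"], strictly = TRUE))
      stop_cfg("mean curve '", nm, "' months must be strictly increasing")
  }
  if (cfg$visit_interval < 1L) stop_cfg("visit_interval must be >= 1 month")
  if (cfg$hazard_base < 0) stop_cfg("hazard_base must be non-negative")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic ART cohort configuration\n")
  cat(sprintf("  patients: %d, follow-up: %d months, visits every %d months\n",
              x$n_patients, x$max_month, x$visit_interval))
  cat(sprintf("  mean classes (cH/HsD/DrI): %s\n",
              paste(sprintf("%.3f", x$mean_class_probs), collapse = "/")))
  cat(sprintf("  variance strata (L/M/H) SDs: %s\n",
              paste(x$noise_sd_by_var_class, collapse = "/")))
  cat(sprintf("  hazard: base %.4f, HR %.2f per 10 pts mean, HR %.2f per z unit\n",
              x$hazard_base, exp(x$log_hr_mean_per_10pct),
              exp(x$log_hr_stdvar_per_unit)))
  invisible(x)
}

## Interpolate a class mean curve onto integer months 1..max_month.
mean_curve_values <- function(curve, max_month) {
  stats::approx(curve[, "month"], curve[, "adherence"],
                xout = seq_len(max_month), rule = 2)$y
}

## Labels shared across the package. Mean classes are ordered by curve level
## in the first year (cH highest), variance classes by noise level.
mean_class_labels <- function() c("cH", "HsD", "DrI")
var_class_labels <- function() c("Low", "Moderate", "High")
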