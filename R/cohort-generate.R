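#' Generate a synthetic ART adherence cohort
#'
#' Simulates a cohort with the latent structure the downstream analysis
#' assumes. For each patient a mean-trajectory class and a variability
#' stratum are drawn independently; monthly adherence is the class curve
#' plus Gaussian noise with the stratum-specific SD, truncated to
#' \[0, 100\] and rounded to pill-count precision (2 decimals). Laboratory
#' visits every `visit_interval` months carry a CD4 count (baseline plus a
#' class-specific linear trend plus measurement noise) and a viral load
#' whose probability of being undetectable (< 1000 copies/mL) follows the
#' configured cell log-odds plus a shared six-month-period random effect.
#'
#' Death is simulated on the monthly grid from month 12: during month
#' `(m, m+1]` the discrete hazard is
#' `hazard_base * exp(log_hr_mean_per_10pct * mean_m / 10 +
#' log_hr_stdvar_per_unit * z_m)` where `mean_m` and `z_m` are the patient's
#' current 12-month moving mean and population-standardized moving variance
#' (computed with [moving_mean_variance()] and [standardize_variances()]
#' over the whole simulated cohort). Follow-up is administratively censored
#' at `max_month`. No adherence or visit record is emitted after death.
#'
#' Randomness is organised as one splittable L'Ecuyer-CMRG stream per
#' patient (plus a cohort-level stream for shared period effects), so the
#' first k patients of a cohort are identical whenever only `n_patients`
#' grows, and death draws are coupled across configurations that share a
#' seed (useful for monotonicity checks on the hazard parameters).
#'
#' @param config a [cohort_config()].
#' @return object of class `sim_cohort`: a list with data frames
#'   `adherence` (patient_id, month, adherence), `visits` (patient_id,
#'   month, cd4, viral_load), `survival` (patient_id, time_month, event),
#'   `truth` (patient_id, true_mean_class, true_var_class; integer codes
#'   1=cH/Low ... 3=DrI/High), diagnostic element `hazard` (per
#'   patient-month discrete hazard along the full pre-death covariate path)
#'   and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  M <- config$max_month
  streams <- rng_streams(config$seed, n + 1L)
  cohort_stream <- streams[[1L]]

  ## Shared six-month-period random effects for the undetectable-VL logit.
  n_periods <- ceiling(M / 6)
  period_re <- with_rng_state(cohort_stream,
                              stats::rnorm(n_periods, 0, config$vl_period_sd))

  curve_mat <- vapply(config$mean_curves, mean_curve_values,
                      numeric(M), max_month = M)  # M x 3 (cH, HsD, DrI)

  visit_months <- seq(0L, M, by = config$visit_interval)

  mean_class <- integer(n); var_class <- integer(n)
  adh <- matrix(NA_real_, nrow = n, ncol = M)
  cd4_mat <- matrix(NA_real_, nrow = n, ncol = length(visit_months))
  vl_mat <- matrix(NA_real_, nrow = n, ncol = length(visit_months))
  death_u <- matrix(NA_real_, nrow = n, ncol = M)

  for (i in seq_len(n)) {
    s_pat <- streams[[i + 1L]]
    s_adh <- parallel::nextRNGSubStream(s_pat)
    s_lab <- parallel::nextRNGSubStream(s_adh)
    s_die <- parallel::nextRNGSubStream(s_lab)

    cls <- with_rng_state(s_pat, {
      c(findInterval(stats::runif(1), cumsum(config$mean_class_probs)) + 1L,
        findInterval(stats::runif(1), cumsum(config$var_class_probs)) + 1L)
    })
    mean_class[i] <- min(cls[1L], 3L)
    var_class[i] <- min(cls[2L], 3L)

    noise_sd <- config$noise_sd_by_var_class[var_class[i]]
    adh[i, ] <- with_rng_state(s_adh, {
      a <- curve_mat[, mean_class[i]] + stats::rnorm(M, 0, noise_sd)
      round(pmin(100, pmax(0, a)), 2)
    })

    lab <- with_rng_state(s_lab, {
      base_cd4 <- stats::rnorm(1, config$cd4_baseline_mean, config$cd4_baseline_sd)
      cd4 <- base_cd4 + config$cd4_slope_by_class[mean_class[i]] * visit_months +
        stats::rnorm(length(visit_months), 0, config$cd4_visit_sd)
      cd4 <- round(pmax(5, cd4), 1)
      u_det <- stats::runif(length(visit_months))
      u_val <- stats::runif(length(visit_months))
      list(cd4 = cd4, u_det = u_det, u_val = u_val)
    })
    cd4_mat[i, ] <- lab$cd4
    ## Undetectable probability: cell log-odds + period effect; at therapy
    ## start (month 0) detectable VL is near-certain.
    logit <- vapply(visit_months, function(m) {
      if (m == 0L) return(-4)
      config$vl_logit[mean_class[i], var_class[i]] + period_re[ceiling(m / 6)]
    }, numeric(1))
    undet <- lab$u_det < stats::plogis(logit)
    vl_mat[i, ] <- ifelse(undet,
                          round(exp(log(50) + lab$u_val * (log(999) - log(50)))),
                          round(exp(log(1000) + lab$u_val * (log(3e5) - log(1000)))))

    death_u[i, ] <- with_rng_state(s_die, stats::runif(M))
  }

  ## Moving statistics along the full (pre-death) paths drive the hazard.
  adh_long <- data.frame(
    patient_id = rep(patient_ids(n), each = M),
    month = rep(seq_len(M), times = n),
    adherence = as.vector(t(adh)))
  hazard <- NULL
  death_month <- rep(NA_integer_, n)
  if (n > 0L) {
    mv <- moving_mean_variance(adh_long, window = 12L)
    std <- standardize_variances(mv)
    pts <- std$points
    ## n x M lookup of moving mean and standardized variance (months >= 12).
    idx <- match(pts$patient_id, patient_ids(n))
    mean_path <- matrix(NA_real_, n, M); z_path <- matrix(NA_real_, n, M)
    mean_path[cbind(idx, pts$month)] <- pts$moving_mean
    z_path[cbind(idx, pts$month)] <- pts$std_variance

    lam <- config$hazard_base *
      exp(config$log_hr_mean_per_10pct * mean_path / 10 +
          config$log_hr_stdvar_per_unit * z_path)
    lam <- pmin(lam, 1)
    ## Death during (m, m+1] for the first m in 12..M-1 with u_m < lambda_m.
    for (i in seq_len(n)) {
      mm <- seq(12L, M - 1L)
      hit <- mm[which(death_u[i, mm] < lam[i, mm])]
      if (length(hit)) death_month[i] <- hit[1L] + 1L
    }
    hazard <- data.frame(
      patient_id = rep(patient_ids(n), each = M - 12L),
      month = rep(seq(12L, M - 1L), times = n),
      hazard = as.vector(t(lam[, seq(12L, M - 1L), drop = FALSE])))
  }

  ## Truncate observations at death / administrative censoring.
  event <- !is.na(death_month)
  time_month <- ifelse(event, death_month, M)
  last_adh <- ifelse(event, death_month - 1L, M)

  keep_adh <- adh_long$month <= last_adh[match(adh_long$patient_id, patient_ids(n))]
  adherence <- adh_long[keep_adh, , drop = FALSE]
  rownames(adherence) <- NULL

  visits <- data.frame(
    patient_id = rep(patient_ids(n), each = length(visit_months)),
    month = rep(visit_months, times = n),
    cd4 = as.vector(t(cd4_mat)),
    viral_load = as.vector(t(vl_mat)))
  keep_vis <- visits$month < time_month[match(visits$patient_id, patient_ids(n))] |
    (!event[match(visits$patient_id, patient_ids(n))] & visits$month <= M)
  visits <- visits[keep_vis, , drop = FALSE]
  rownames(visits) <- NULL

  out <- list(
    adherence = adherence,
    visits = visits,
    survival = data.frame(patient_id = patient_ids(n),
                          time_month = as.integer(time_month),
                          event = as.integer(event)),
    truth = data.frame(patient_id = patient_ids(n),
                       true_mean_class = mean_class,
                       true_var_class = var_class),
    hazard = hazard,
    config = config)
  if (n == 0L) {
    out$adherence <- data.frame(patient_id = character(), month = integer(),
                                adherence = numeric())
    out$visits <- data.frame(patient_id = character(), month = integer(),
                             cd4 = numeric(), viral_load = numeric())
  }
  class(out) <- "sim_cohort"
  out
}

patient_ids <- function(n) sprintf("P%04d", seq_len(n))

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ART cohort: %d patients, %d adherence records, %d visits\n",
              nrow(x$survival), nrow(x$adherence), nrow(x$visits)))
  if (nrow(x$survival))
    cat(sprintf("  deaths: %d (%.1f%%), follow-up censored at %d months\n",
                sum(x$survival$event), 100 * mean(x$survival$event),
                x$config$max_month))
  invisible(x)
}
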