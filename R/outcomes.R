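#' Build six-month immunovirological outcomes
#'
#' Assigns each laboratory visit at month `m` to six-month period
#' `ceiling(m / 6)`, excludes the therapy-initiation baseline (month 0,
#' period 0) from the outcome records, flags undetectable viral load
#' (strictly below `threshold` copies/mL) and computes the monthly CD4
#' change between consecutive periods, `(CD4_p - CD4_{p-1}) / 6`
#' (cells/mm3/month; the baseline CD4 may serve as the `p - 1 = 0` value).
#' When a patient has two visits in one period the later one is kept, with
#' a warning.
#'
#' @param visits data frame `patient_id`, `month`, `cd4`, `viral_load`.
#' @param classes data frame `patient_id`, `mean_class` (1=cH, 2=HsD,
#'   3=DrI), `var_class` (1=Low, 2=Moderate, 3=High).
#' @param threshold viral-load detectability threshold (copies/mL).
#' @return data frame `patient_id`, `period`, `mean_class`, `var_class`
#'   (labelled factors with reference levels DrI and High),
#'   `undetectable` (logical), `cd4_monthly_change` (NA when the previous
#'   period's visit is missing).
#' @export
build_six_month_outcomes <- function(visits, classes, threshold = 1000) {
  stopifnot(all(c("patient_id", "month", "cd4", "viral_load") %in% names(visits)),
            all(c("patient_id", "mean_class", "var_class") %in% names(classes)))
  visits <- visits[order(visits$patient_id, visits$month), , drop = FALSE]
  visits$period <- ceiling(visits$month / 6)
  key <- paste(visits$patient_id, visits$period)
  dup <- duplicated(key, fromLast = TRUE)  # keep the later visit
  if (any(dup))
    warning(sum(dup), " visit(s) superseded by a later visit in the same period")
  visits <- visits[!dup, , drop = FALSE]

  ## CD4 change between consecutive periods (within patient).
  visits$cd4_monthly_change <- NA_real_
  sp <- split(seq_len(nrow(visits)), visits$patient_id)
  for (idx in sp) {
    p <- visits$period[idx]
    prev <- match(p - 1, p)
    ok <- !is.na(prev)
    visits$cd4_monthly_change[idx[ok]] <-
      (visits$cd4[idx[ok]] - visits$cd4[idx[prev[ok]]]) / 6
  }

  out <- visits[visits$period >= 1, , drop = FALSE]
  m <- match(out$patient_id, classes$patient_id)
  if (anyNA(m))
    stop_cfg("visits contain patients absent from the class table: ",
             paste(utils::head(unique(out$patient_id[is.na(m)]), 5L),
                   collapse = ", "))
  out$mean_class <- factor(mean_class_labels()[classes$mean_class[m]],
                           levels = c("DrI", "HsD", "cH"))
  out$var_class <- factor(var_class_labels()[classes$var_class[m]],
                          levels = c("High", "Moderate", "Low"))
  out$undetectable <- out$viral_load < threshold
  out <- out[, c("patient_id", "period", "mean_class", "var_class",
                 "undetectable", "cd4_monthly_change")]
  rownames(out) <- NULL
  out
}

#' Mixed logistic regression for undetectable viral load
#'
#' Models the per patient-period indicator of undetectable viral load on
#' the full mean-class x variance-class interaction (reference cell: DrI
#' average adherence with High variance) with a random intercept on the
#' six-month period. With fewer than two periods the random intercept is
#' inestimable and the model reduces to an ordinary logistic regression
#' (with a warning).
#'
#' @param outcomes from [build_six_month_outcomes()].
#' @return data frame of effect estimates: `term`, `estimate` (log-odds),
#'   `ratio` (odds ratio), `ci_low`, `ci_high` (95\% Wald, ratio scale),
#'   `level`, `model`.
#' @export
fit_mixed_logistic <- function(outcomes) {
  d <- outcomes[!is.na(outcomes$undetectable), , drop = FALSE]
  d <- droplevels(d)
  if (nlevels(d$mean_class) < 2L && nlevels(d$var_class) < 2L)
    stop_cfg("need at least two class levels to fit effects")
  single_period <- length(unique(d$period)) < 2L
  if (single_period) {
    warning("single six-month period: fitting ordinary logistic regression")
    m <- stats::glm(undetectable ~ mean_class * var_class, data = d,
                    family = stats::binomial())
    co <- summary(m)$coefficients[, 1:2, drop = FALSE]
  } else {
    m <- lme4::glmer(undetectable ~ mean_class * var_class + (1 | period),
                     data = d, family = stats::binomial(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
    co <- cbind(lme4::fixef(m), sqrt(diag(as.matrix(stats::vcov(m)))))
  }
  effects_table(co, ratio_label = "OR", model = "mixed_logistic")
}

#' Mixed linear model for monthly CD4 change
#'
#' Models the monthly CD4 change (cells/mm3/month) on the full mean-class x
#' variance-class interaction (reference cell: DrI x High) with a random
#' intercept on the six-month period; ordinary least squares with fewer
#' than two periods.
#'
#' @param outcomes from [build_six_month_outcomes()].
#' @return data frame of effect estimates (`ratio` is `NA`; estimates are
#'   in cells/mm3/month with 95\% Wald CIs on the estimate scale).
#' @export
fit_mixed_linear <- function(outcomes) {
  d <- outcomes[!is.na(outcomes$cd4_monthly_change), , drop = FALSE]
  d <- droplevels(d)
  single_period <- length(unique(d$period)) < 2L
  if (single_period) {
    warning("single six-month period: fitting ordinary linear regression")
    m <- stats::lm(cd4_monthly_change ~ mean_class * var_class, data = d)
    co <- summary(m)$coefficients[, 1:2, drop = FALSE]
  } else {
    m <- lme4::lmer(cd4_monthly_change ~ mean_class * var_class + (1 | period),
                    data = d)
    co <- cbind(lme4::fixef(m), sqrt(diag(as.matrix(stats::vcov(m)))))
  }
  effects_table(co, ratio_label = NA_character_, model = "mixed_linear")
}

effects_table <- function(co, ratio_label, model) {
  z <- stats::qnorm(0.975)
  est <- co[, 1L]; se <- co[, 2L]
  on_ratio <- !is.na(ratio_label)
  data.frame(
    term = rownames(co),
    estimate = unname(est),
    ratio = if (on_ratio) exp(unname(est)) else NA_real_,
    ci_low = unname(if (on_ratio) exp(est - z * se) else est - z * se),
    ci_high = unname(if (on_ratio) exp(est + z * se) else est + z * se),
    level = 0.95,
    model = model,
    row.names = NULL)
}

#' Monthly counting-process episodes with time-varying adherence covariates
#'
#' Expands each patient's follow-up into monthly episodes `(m, m + 1]`
#' carrying that month's moving mean (per 10 adherence points) and
#' standardized variance, with late entry at month 12 (moving covariates do
#' not exist earlier) and the death event on the final episode. Patients
#' dying or censored at or before month 12 are excluded with a warning.
#' Months with no moving point carry the last preceding value forward; a
#' patient's leading months without any value are dropped (deferred entry).
#'
#' @param moving data frame `patient_id`, `month`, `moving_mean`,
#'   `std_variance` (e.g. the standardized output of
#'   [standardize_variances()]).
#' @param survival data frame `patient_id`, `time_month`, `event`.
#' @return data frame `patient_id`, `start`, `stop`, `event`,
#'   `moving_mean_per10`, `std_variance`.
#' @export
build_survival_episodes <- function(moving, survival) {
  stopifnot(all(c("patient_id", "month", "moving_mean", "std_variance")
                %in% names(moving)),
            all(c("patient_id", "time_month", "event") %in% names(survival)))
  early <- survival$time_month <= 12
  if (any(early))
    warning(sum(early), " patient(s) with follow-up <= 12 months excluded ",
            "(no moving-covariate history)")
  surv <- survival[!early, , drop = FALSE]
  mv_by_pat <- split(moving, moving$patient_id)
  pieces <- lapply(seq_len(nrow(surv)), function(i) {
    pid <- surv$patient_id[i]
    tm <- surv$time_month[i]
    mv <- mv_by_pat[[pid]]
    if (is.null(mv)) return(NULL)
    mv <- mv[order(mv$month), , drop = FALSE]
    months <- seq(12L, tm - 1L)
    pos <- findInterval(months, mv$month)   # LOCF
    keep <- pos >= 1L
    if (!any(keep)) return(NULL)
    months <- months[keep]; pos <- pos[keep]
    data.frame(patient_id = pid, start = months, stop = months + 1L,
               event = as.integer(surv$event[i] == 1L &
                                    months + 1L == tm),
               moving_mean_per10 = mv$moving_mean[pos] / 10,
               std_variance = mv$std_variance[pos])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    return(data.frame(patient_id = character(), start = integer(),
                      stop = integer(), event = integer(),
                      moving_mean_per10 = numeric(), std_variance = numeric()))
  rownames(out) <- NULL
  out
}

#' Time-dependent Cox model for mortality
#'
#' Fits a proportional-hazards model on the monthly counting-process
#' episodes, with the moving mean of adherence (per 10 points) and/or the
#' standardized variance as time-varying covariates, optionally with their
#' interaction. Ties (frequent on the monthly grid) are handled by the
#' Efron approximation by default.
#'
#' @param episodes from [build_survival_episodes()].
#' @param terms one of `"both"` (default), `"mean"`, `"variance"`,
#'   `"interaction"` (both plus their product).
#' @param ties `"efron"` or `"breslow"`.
#' @return data frame of effect estimates (`ratio` = hazard ratio), plus
#'   attribute `"fit"` carrying the `coxph` object.
#' @export
fit_cox_td <- function(episodes, terms = c("both", "mean", "variance",
                                           "interaction"),
                       ties = c("efron", "breslow")) {
  terms <- match.arg(terms)
  ties <- match.arg(ties)
  if (sum(episodes$event) < 1L) stop_cfg("no events in episodes")
  rhs <- switch(terms,
                mean = "moving_mean_per10",
                variance = "std_variance",
                both = "moving_mean_per10 + std_variance",
                interaction = "moving_mean_per10 * std_variance")
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, event) ~", rhs))
  m <- survival::coxph(fml, data = episodes, ties = ties)
  if (!is.null(m$iter) && m$iter >= 20L)
    warning("possible non-convergence: coxph used ", m$iter, " iterations")
  co <- cbind(stats::coef(m), sqrt(diag(stats::vcov(m))))
  out <- effects_table(co, ratio_label = "HR", model = paste0("cox_", terms))
  attr(out, "fit") <- m
  out
}
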