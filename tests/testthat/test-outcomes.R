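toy_classes <- function(ids, mean_class = 3L, var_class = 3L) {
  data.frame(patient_id = ids, mean_class = mean_class, var_class = var_class)
}

test_that("six-month outcomes apply the strict threshold, period rule and CD4 change", {
  visits <- data.frame(
    patient_id = "A",
    month = c(0, 6, 12, 18),
    cd4 = c(250, 300, 360, 360),
    viral_load = c(50000, 999, 1000, 400))
  out <- build_six_month_outcomes(visits, toy_classes("A"))
  ## baseline month 0 excluded; periods 1..3 kept
  expect_equal(out$period, c(1, 2, 3))
  ## VL 999 undetectable, VL 1000 detectable (strict < 1000)
  expect_equal(out$undetectable, c(TRUE, FALSE, TRUE))
  ## (360 - 300)/6 = 10 cells/mm3/month; period-1 change uses baseline CD4
  expect_equal(out$cd4_monthly_change, c((300 - 250) / 6, 10, 0))
  expect_equal(levels(out$mean_class), c("DrI", "HsD", "cH"))
  expect_equal(levels(out$var_class), c("High", "Moderate", "Low"))
})

test_that("duplicate visits within a period keep the later one with a warning", {
  visits <- data.frame(patient_id = "A", month = c(4, 6, 12),
                       cd4 = c(100, 200, 260), viral_load = c(2000, 500, 500))
  expect_warning(out <- build_six_month_outcomes(visits, toy_classes("A")),
                 "superseded")
  expect_equal(nrow(out), 2)
  expect_equal(out$cd4_monthly_change, c(NA_real_, 10))
})

test_that("empirical undetectable share in a cell follows its configured probability", {
  cfg <- cohort_config(n_patients = 150, seed = 91, hazard_base = 0,
                       vl_logit = matrix(qlogis(0.7), 3, 3,
                                         dimnames = list(c("cH", "HsD", "DrI"),
                                                         c("Low", "Moderate", "High"))),
                       vl_period_sd = 0)
  co <- generate_cohort(cfg)
  out <- build_six_month_outcomes(
    co$visits, toy_classes(co$truth$patient_id,
                           co$truth$true_mean_class, co$truth$true_var_class))
  n <- sum(!is.na(out$undetectable))
  phat <- mean(out$undetectable)
  expect_lt(abs(phat - 0.7), 1.96 * sqrt(0.7 * 0.3 / n) + 0.01)
})

test_that("with a single period the mixed logistic model reduces to plain logistic regression", {
  set.seed(5)
  n <- 400
  d <- data.frame(
    patient_id = sprintf("P%03d", 1:n), period = 1L,
    mean_class = factor(sample(c("DrI", "HsD", "cH"), n, TRUE),
                        levels = c("DrI", "HsD", "cH")),
    var_class = factor(sample(c("High", "Moderate", "Low"), n, TRUE),
                       levels = c("High", "Moderate", "Low")),
    cd4_monthly_change = NA_real_)
  eta <- 0.3 + 0.8 * (d$mean_class == "cH") - 0.4 * (d$var_class == "Low")
  d$undetectable <- runif(n) < plogis(eta)
  expect_warning(eff <- fit_mixed_logistic(d), "single six-month period")
  X <- model.matrix(~ mean_class * var_class, d)
  b_oracle <- oracle_logistic(X, as.numeric(d$undetectable))
  expect_equal(eff$estimate, unname(b_oracle), tolerance = 1e-4)
  expect_equal(eff$ratio, exp(eff$estimate))
  expect_true(all(eff$ci_low <= eff$ratio & eff$ratio <= eff$ci_high))
})

test_that("a constant CD4 change is fitted with intercept equal to the constant", {
  d <- expand.grid(patient_id = sprintf("P%02d", 1:30),
                   period = 1L, KEEP.OUT.ATTRS = FALSE)
  d$mean_class <- factor(rep(c("DrI", "HsD", "cH"), 10),
                         levels = c("DrI", "HsD", "cH"))
  d$var_class <- factor(rep(c("High", "Moderate", "Low"), each = 10),
                        levels = c("High", "Moderate", "Low"))
  d$undetectable <- TRUE
  d$cd4_monthly_change <- 5
  w <- capture_warnings(eff <- fit_mixed_linear(d))
  expect_true(any(grepl("single six-month period", w)))
  expect_equal(eff$estimate[eff$term == "(Intercept)"], 5, tolerance = 1e-8)
  expect_true(all(abs(eff$estimate[eff$term != "(Intercept)"]) < 1e-8))
})

test_that("survival episodes carry monthly covariates with correct bookkeeping", {
  mv <- data.frame(patient_id = rep(c("A", "B"), each = 3),
                   month = rep(12:14, 2),
                   moving_mean = c(90, 91, 92, 70, 71, 72),
                   std_variance = c(0.1, 0.2, 0.3, -0.1, -0.2, -0.3))
  surv <- data.frame(patient_id = c("A", "B"), time_month = c(14, 13),
                     event = c(0L, 1L))
  ep <- build_survival_episodes(mv, surv)
  a <- ep[ep$patient_id == "A", ]
  expect_equal(a$start, c(12, 13))
  expect_equal(a$stop, c(13, 14))
  expect_equal(a$event, c(0L, 0L))
  expect_equal(a$moving_mean_per10, c(9.0, 9.1))
  b <- ep[ep$patient_id == "B", ]
  expect_equal(nrow(b), 1)
  expect_equal(b$event, 1L)
  expect_equal(b$start, 12)

  ## early death excluded with warning
  surv2 <- rbind(surv, data.frame(patient_id = "C", time_month = 10,
                                  event = 1L))
  expect_warning(ep2 <- build_survival_episodes(mv, surv2), "excluded")
  expect_false("C" %in% ep2$patient_id)
})

test_that("person-time and events are conserved exactly on a simulated cohort", {
  co <- generate_cohort(cohort_config(n_patients = 50, seed = 15))
  mv <- moving_mean_variance(co$adherence)
  std <- standardize_variances(mv)
  ep <- build_survival_episodes(std$points, co$survival)
  included <- co$survival[co$survival$time_month > 12, ]
  expect_equal(sum(ep$stop - ep$start),
               sum(pmin(included$time_month, 108) - 12))
  expect_equal(sum(ep$event), sum(included$event))
})

test_that("the Cox partial likelihood maximum matches the closed-form toy solution", {
  ## three patients, constant covariates 0/1/3 (per 10 points), one death
  ## at month 20 with all three at risk: the score equation
  ## exp(b) + 3 exp(3b) = 1 + exp(b) + exp(3b) gives b = -log(2)/3.
  mv <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(patient_id = c("A", "B", "C")[i], month = 12:29,
               moving_mean = c(0, 10, 30)[i], std_variance = 0)
  }))
  surv <- data.frame(patient_id = c("A", "B", "C"),
                     time_month = c(25, 20, 30), event = c(0L, 1L, 0L))
  ep <- build_survival_episodes(mv, surv)
  eff <- fit_cox_td(ep, terms = "mean")
  b_closed <- -log(2) / 3
  expect_equal(eff$estimate, b_closed, tolerance = 1e-6)
  ## independent numeric maximization of the same partial likelihood
  b_opt <- optimize(function(b) oracle_cox_logpl(b, ep, "moving_mean_per10"),
                    c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(eff$estimate, b_opt, tolerance = 1e-6)
  expect_equal(eff$ratio, exp(eff$estimate))
})

test_that("a covariate unrelated to the hazard has HR near 1", {
  ## many events (high baseline hazard, no covariate effects) so the
  ## Monte-Carlo band of the null HR sits well inside [0.9, 1.1]
  cfg <- cohort_config(n_patients = 2000, seed = 17,
                       hazard_base = 0.01,
                       log_hr_mean_per_10pct = 0,
                       log_hr_stdvar_per_unit = 0)
  co <- generate_cohort(cfg)
  mv <- moving_mean_variance(co$adherence)
  std <- standardize_variances(mv)
  ep <- build_survival_episodes(std$points, co$survival)
  eff <- fit_cox_td(ep, terms = "both")
  hr_z <- eff$ratio[eff$term == "std_variance"]
  expect_gt(hr_z, 0.9)
  expect_lt(hr_z, 1.1)
})

test_that("adjusted and unadjusted hazard ratios agree for decorrelated covariates", {
  cfg <- cohort_config(n_patients = 1000, seed = 19)
  co <- generate_cohort(cfg)
  mv <- moving_mean_variance(co$adherence)
  std <- standardize_variances(mv)
  ep <- build_survival_episodes(std$points, co$survival)
  both <- fit_cox_td(ep, terms = "both")
  uni <- fit_cox_td(ep, terms = "mean")
  expect_lt(abs(both$ratio[both$term == "moving_mean_per10"] - uni$ratio), 0.05)
  ## no-event input errors
  ep0 <- ep[ep$event == 0, ]
  expect_error(fit_cox_td(ep0), "no events")
})
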