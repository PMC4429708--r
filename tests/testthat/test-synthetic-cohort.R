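test_that("invalid configurations are rejected", {
  expect_error(cohort_config(mean_class_probs = c(0.5, 0.4, 0.2)),
               "summing to 1")
  expect_error(cohort_config(var_class_probs = c(0.5, 0.6, -0.1)),
               "probabilities")
  expect_error(cohort_config(noise_sd_by_var_class = c(5, 3, 8)),
               "strictly increasing")
  expect_error(cohort_config(noise_sd_by_var_class = c(-1, 3, 8)),
               "non-negative")
  expect_error(cohort_config(max_month = 12), "max_month")
  curves <- default_mean_curves()
  curves$cH[, "adherence"] <- 105
  expect_error(cohort_config(mean_curves = curves), "\\[0, 100\\]")
})

test_that("generation is deterministic and append-stable in the patient streams", {
  cfg <- cohort_config(n_patients = 30, seed = 77, hazard_base = 0)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$adherence, b$adherence)
  expect_identical(a$visits, b$visits)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth, b$truth)
  ## appending patients must not disturb earlier patients' draws
  big <- generate_cohort(cohort_config(n_patients = 45, seed = 77,
                                       hazard_base = 0))
  keep <- big$adherence$patient_id %in% a$adherence$patient_id
  sub <- big$adherence[keep, ]
  rownames(sub) <- NULL
  expect_identical(sub, a$adherence)
  expect_identical(big$truth[1:30, ], a$truth)
})

test_that("zero noise gives exactly zero moving variance and curve-valued adherence", {
  flat <- list(cH = cbind(month = c(0, 108), adherence = c(95, 95)),
               HsD = cbind(month = c(0, 108), adherence = c(90, 90)),
               DrI = cbind(month = c(0, 108), adherence = c(80, 80)))
  cfg <- cohort_config(n_patients = 8, seed = 3, mean_curves = flat,
                       noise_sd_by_var_class = c(0, 0, 0), hazard_base = 0)
  co <- generate_cohort(cfg)
  mv <- moving_mean_variance(co$adherence)
  expect_true(all(mv$moving_variance == 0))
  expect_true(all(co$adherence$adherence >= 0 & co$adherence$adherence <= 100))
})

test_that("with null covariate effects the mean classes share one survival curve", {
  pvals <- vapply(1:12, function(s) {
    cfg <- cohort_config(n_patients = 120, seed = 4000 + s,
                         hazard_base = 0.002,
                         log_hr_mean_per_10pct = 0,
                         log_hr_stdvar_per_unit = 0)
    co <- generate_cohort(cfg)
    cls <- co$truth$true_mean_class[match(co$survival$patient_id,
                                          co$truth$patient_id)]
    sd <- survival::survdiff(
      survival::Surv(co$survival$time_month, co$survival$event) ~ cls)
    1 - stats::pchisq(sd$chisq, length(sd$n) - 1)
  }, numeric(1))
  ## log-rank p-values should look uniform, not concentrated near zero
  expect_lte(sum(pvals < 0.05), 3)
  expect_gt(mean(pvals), 0.2)
})

test_that("empirical death fraction matches the discrete-hazard product oracle", {
  cfg <- cohort_config(n_patients = 1000, seed = 2024)
  co <- generate_cohort(cfg)
  ## oracle: P(death) = 1 - prod_m (1 - lambda_m) along each covariate path
  p_death <- vapply(split(co$hazard$hazard, co$hazard$patient_id),
                    function(h) 1 - prod(1 - h), numeric(1))
  expected <- mean(p_death)
  mc_se <- sqrt(sum(p_death * (1 - p_death))) / length(p_death)
  observed <- mean(co$survival$event)
  expect_lt(abs(observed - expected), 3.5 * mc_se)
})

test_that("raising the variability hazard coefficient increases deaths in expectation", {
  diffs <- vapply(1:20, function(s) {
    lo <- generate_cohort(cohort_config(n_patients = 150, seed = 900 + s))
    hi <- generate_cohort(cohort_config(n_patients = 150, seed = 900 + s,
                                        log_hr_stdvar_per_unit = log(4)))
    sum(hi$survival$event) - sum(lo$survival$event)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("class-conditional adherence means track the configured curves", {
  curves <- list(
    cH  = cbind(month = c(0, 108), adherence = c(80, 80)),
    HsD = cbind(month = c(0, 48, 108), adherence = c(75, 75, 55)),
    DrI = cbind(month = c(0, 12, 36, 84, 108), adherence = c(70, 70, 40, 75, 75)))
  cfg <- cohort_config(n_patients = 400, seed = 5, mean_curves = curves,
                       noise_sd_by_var_class = c(2, 4, 6), hazard_base = 0)
  co <- generate_cohort(cfg)
  truth_of <- co$truth$true_mean_class[match(co$adherence$patient_id,
                                             co$truth$patient_id)]
  for (m in c(12, 36, 84)) {
    sel <- co$adherence$month == m
    for (k in 1:3) {
      vals <- co$adherence$adherence[sel & truth_of == k]
      target <- stats::approx(curves[[k]][, 1], curves[[k]][, 2], m,
                              rule = 2)$y
      se <- stats::sd(vals) / sqrt(length(vals))
      expect_lt(abs(mean(vals) - target), 2 * se + 1e-9)
    }
  }
})

test_that("cohort files round-trip exactly, including empty and tiny cohorts", {
  dir0 <- withr::local_tempdir()
  empty <- generate_cohort(cohort_config(n_patients = 0, seed = 1))
  write_cohort(empty, dir0)
  back <- read_cohort(dir0)
  expect_equal(nrow(back$adherence), 0)
  expect_equal(nrow(back$survival), 0)

  dir1 <- withr::local_tempdir()
  one <- generate_cohort(cohort_config(n_patients = 1, seed = 8))
  write_cohort(one, dir1)
  b1 <- read_cohort(dir1)
  expect_equal(b1$adherence, one$adherence)
  expect_equal(b1$visits, one$visits)
  expect_equal(b1$survival, one$survival)
  expect_equal(b1$truth, one$truth)

  dir2 <- withr::local_tempdir()
  dir3 <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_patients = 100, seed = 12))
  write_cohort(co, dir2)
  write_cohort(co, dir3)
  for (f in c("adherence.csv", "visits.csv", "survival.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(dir2, f))),
                     unname(tools::md5sum(file.path(dir3, f))))
  }
  b2 <- read_cohort(dir2)
  expect_equal(b2$adherence, co$adherence)
  expect_equal(b2$visits, co$visits)
})

test_that("malformed cohort files are rejected with the offending row named", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_patients = 2, seed = 4))
  write_cohort(co, dir)
  adh <- utils::read.csv(file.path(dir, "adherence.csv"),
                         colClasses = "character")
  adh$adherence[3] <- "not-a-number"
  utils::write.csv(adh, file.path(dir, "adherence.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_cohort(dir), "row 3")

  write_cohort(co, dir)
  adh <- utils::read.csv(file.path(dir, "adherence.csv"))
  adh <- rbind(adh, adh[1, ])
  utils::write.csv(adh, file.path(dir, "adherence.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_cohort(dir), "duplicated patient-month")
})
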