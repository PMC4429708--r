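#' Configure an end-to-end analysis run
#'
#' Bundles all stage configurations for [run_pipeline()]. Stages run in the
#' fixed order `simulate`, `moving`, `trajectories`, `outcomes`, `report`;
#' any subset may be enabled. When `simulate` is disabled the input files
#' (`adherence.csv`, `visits.csv`, `survival.csv`) must already exist in
#' `outdir`.
#'
#' @param outdir output (and input) directory.
#' @param seed master seed; all stage randomness derives from it.
#' @param stages character vector of stages to run.
#' @param cohort a [cohort_config()] for the `simulate` stage (its `seed`
#'   is overridden by the pipeline seed).
#' @param window moving-window length in months.
#' @param target_class_size target bin size for variance standardization.
#' @param n_classes,n_starts,max_iter,tol,m_step_maxit latent-class fitting
#'   controls (see [fit_lcmm()]).
#' @param fit_month_step fit trajectories on every `fit_month_step`-th
#'   month of the moving series (1 = all months); thinning trades a little
#'   statistical efficiency for speed on long series.
#' @param vl_threshold viral-load detectability threshold (copies/mL).
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            stages = c("simulate", "moving", "trajectories",
                                       "outcomes", "report"),
                            cohort = cohort_config(),
                            window = 12L,
                            target_class_size = 30L,
                            n_classes = 3L,
                            n_starts = 4L,
                            max_iter = 200L,
                            tol = 1e-6,
                            m_step_maxit = 10L,
                            fit_month_step = 1L,
                            vl_threshold = 1000,
                            ties = c("efron", "breslow"),
                            log_level = c("info", "quiet")) {
  known <- c("simulate", "moving", "trajectories", "outcomes", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_cfg("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 stages = known[known %in% stages],
                 cohort = cohort, window = as.integer(window),
                 target_class_size = as.integer(target_class_size),
                 n_classes = as.integer(n_classes),
                 n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 m_step_maxit = as.integer(m_step_maxit),
                 fit_month_step = as.integer(fit_month_step),
                 vl_threshold = vl_threshold,
                 ties = match.arg(ties),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a plain-text key-value hierarchy and validates it against the
#' known configuration schema; unknown keys are rejected. Nested `cohort:`
#' keys are passed to [cohort_config()].
#'
#' @param path YAML file path.
#' @param outdir,seed optional overrides of the file's values.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path, outdir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "cohort")
  bad <- setdiff(names(raw), c(known, "cohort"))
  if (length(bad))
    stop_cfg("unknown configuration key(s) in ", path, ": ",
             paste(bad, collapse = ", "))
  args <- raw[names(raw) %in% known]
  if (!is.null(raw$cohort)) {
    bad_c <- setdiff(names(raw$cohort), names(formals(cohort_config)))
    if (length(bad_c))
      stop_cfg("unknown cohort key(s): ", paste(bad_c, collapse = ", "))
    args$cohort <- do.call(cohort_config, raw$cohort)
  }
  if (!is.null(outdir)) args$outdir <- outdir
  if (!is.null(seed)) args$seed <- seed
  if (is.null(args$outdir)) stop_cfg("outdir must be given (file or argument)")
  do.call(pipeline_config, args)
}

#' Run the adherence-variability analysis pipeline
#'
#' Executes the enabled stages in order:
#' \describe{
#'   \item{simulate}{generate a synthetic cohort and write
#'     `adherence.csv`, `visits.csv`, `survival.csv`, `truth.csv`;}
#'   \item{moving}{12-month moving mean/variance and the standardized
#'     variance (`moving.csv`, `stdmap.json`);}
#'   \item{trajectories}{latent-class fits of the moving means and of the
#'     standardized variances, posterior matrices and MAP classes
#'     (`model_mean.json`, `model_variance.json`, `posteriors_*.csv`,
#'     `classes_*.csv`);}
#'   \item{outcomes}{six-month outcomes and the three association models
#'     (`outcomes.csv`, `episodes.csv`, `effects.csv`);}
#'   \item{report}{the class cross-tabulation and typical trajectory
#'     curves (`table1.csv`, `trajectories.csv`, `trajectories.pdf`).}
#' }
#' A stage failure aborts the run with an error naming the stage; outputs
#' of completed stages are preserved. Every written file is recorded with
#' its MD5 content hash in `manifest.csv`; an identical configuration and
#' seed reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_msg <- function(...) {
    if (config$log_level == "info")
      message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                      sprintf(...)))
  }
  outputs <- character(0)
  path_of <- function(f) file.path(config$outdir, f)
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    st <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop_cfg("stage '", name, "' failed: ", conditionMessage(e)))
    log_msg("stage %-12s done in %.1fs", name,
            as.numeric(difftime(Sys.time(), st, units = "secs")))
    res
  }

  run_stage("simulate", function() {
    cfg <- config$cohort
    cfg$seed <- config$seed
    cohort <- generate_cohort(cfg)
    write_cohort(cohort, config$outdir)
    outputs <<- c(outputs, "adherence.csv", "visits.csv", "survival.csv",
                  "truth.csv")
  })

  need_inputs <- function(files) {
    for (f in files) if (!file.exists(path_of(f)))
      stop_cfg("required input '", path_of(f), "' does not exist ",
               "(its generating stage is disabled)")
  }

  moving_std <- NULL
  run_stage("moving", function() {
    need_inputs("adherence.csv")
    adh <- read_checked(path_of("adherence.csv"),
                        c("patient_id", "month", "adherence"))
    mv <- moving_mean_variance(adh, window = config$window)
    std <- standardize_variances(mv, config$target_class_size)
    moving_std <<- std
    utils::write.csv(std$points[, c("patient_id", "month", "moving_mean",
                                    "moving_variance", "std_variance")],
                     path_of("moving.csv"), row.names = FALSE, quote = FALSE)
    write_std_map(std$map, path_of("stdmap.json"))
    outputs <<- c(outputs, "moving.csv", "stdmap.json")
  })

  fits <- list()
  run_stage("trajectories", function() {
    need_inputs("moving.csv")
    mv <- utils::read.csv(path_of("moving.csv"))
    mv <- mv[(mv$month - min(mv$month)) %% config$fit_month_step == 0, ]
    fit_one <- function(value, decreasing, tag, seed_offset) {
      d <- data.frame(patient_id = mv$patient_id, month = mv$month,
                      value = value)
      fit <- fit_lcmm(d, n_classes = config$n_classes,
                      n_starts = config$n_starts,
                      seed = config$seed + seed_offset,
                      tol = config$tol, max_iter = config$max_iter,
                      m_step_maxit = config$m_step_maxit)
      fit <- relabel_classes(fit, decreasing = decreasing)
      write_lcmm(fit, path_of(paste0("model_", tag, ".json")))
      post <- data.frame(patient_id = rownames(fit$posterior),
                         round(fit$posterior, 10))
      names(post) <- c("patient_id", paste0("p_", seq_len(config$n_classes)))
      utils::write.csv(post, path_of(paste0("posteriors_", tag, ".csv")),
                       row.names = FALSE, quote = FALSE)
      cls <- map_classify(fit$posterior)
      cls$map_probability <- round(cls$map_probability, 10)
      utils::write.csv(cls, path_of(paste0("classes_", tag, ".csv")),
                       row.names = FALSE, quote = FALSE)
      outputs <<- c(outputs, paste0("model_", tag, ".json"),
                    paste0("posteriors_", tag, ".csv"),
                    paste0("classes_", tag, ".csv"))
      fit
    }
    ## Mean trajectories: class 1 = highest level at month 12 (cH-like).
    fits$mean <<- fit_one(mv$moving_mean, TRUE, "mean", 101L)
    ## Variability trajectories: class 1 = lowest standardized variance.
    fits$variance <<- fit_one(mv$std_variance, FALSE, "variance", 202L)
  })

  run_stage("outcomes", function() {
    need_inputs(c("visits.csv", "survival.csv", "moving.csv",
                  "classes_mean.csv", "classes_variance.csv"))
    visits <- read_checked(path_of("visits.csv"),
                           c("patient_id", "month", "cd4", "viral_load"))
    surv <- read_checked(path_of("survival.csv"),
                         c("patient_id", "time_month", "event"))
    mv <- utils::read.csv(path_of("moving.csv"))
    cm <- utils::read.csv(path_of("classes_mean.csv"))
    cv <- utils::read.csv(path_of("classes_variance.csv"))
    classes <- data.frame(patient_id = cm$patient_id,
                          mean_class = cm$map_class,
                          var_class = cv$map_class[match(cm$patient_id,
                                                         cv$patient_id)])
    outc <- build_six_month_outcomes(visits, classes, config$vl_threshold)
    utils::write.csv(outc, path_of("outcomes.csv"), row.names = FALSE,
                     quote = FALSE)
    episodes <- build_survival_episodes(mv, surv)
    utils::write.csv(episodes, path_of("episodes.csv"), row.names = FALSE,
                     quote = FALSE)
    eff <- rbind(
      suppressMessages(suppressWarnings(fit_mixed_logistic(outc))),
      suppressMessages(suppressWarnings(fit_mixed_linear(outc))),
      fit_cox_td(episodes, terms = "mean", ties = config$ties),
      fit_cox_td(episodes, terms = "variance", ties = config$ties),
      fit_cox_td(episodes, terms = "both", ties = config$ties))
    eff$estimate <- round(eff$estimate, 8)
    eff$ratio <- round(eff$ratio, 8)
    eff$ci_low <- round(eff$ci_low, 8)
    eff$ci_high <- round(eff$ci_high, 8)
    utils::write.csv(eff, path_of("effects.csv"), row.names = FALSE,
                     quote = FALSE)
    outputs <<- c(outputs, "outcomes.csv", "episodes.csv", "effects.csv")
  })

  run_stage("report", function() {
    need_inputs(c("classes_mean.csv", "classes_variance.csv"))
    cm <- utils::read.csv(path_of("classes_mean.csv"))
    cv <- utils::read.csv(path_of("classes_variance.csv"))
    tab <- cross_tabulate(cm, cv)
    utils::write.csv(as.data.frame(tab), path_of("table1.csv"),
                     row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, "table1.csv")
    if (!is.null(fits$mean)) {
      months <- seq(12, max(config$cohort$max_month, 12))
      curves <- do.call(rbind, lapply(seq_len(config$n_classes), function(j) {
        tr <- typical_trajectory(fits$mean, j, months)
        data.frame(series = "moving_mean", class = j, month = tr$month,
                   value = round(tr$value, 6))
      }))
      curves_v <- do.call(rbind, lapply(seq_len(config$n_classes), function(j) {
        tr <- typical_trajectory(fits$variance, j, months)
        data.frame(series = "std_variance", class = j, month = tr$month,
                   value = round(tr$value, 6))
      }))
      curves <- rbind(curves, curves_v)
      utils::write.csv(curves, path_of("trajectories.csv"),
                       row.names = FALSE, quote = FALSE)
      outputs <<- c(outputs, "trajectories.csv")
      grDevices::pdf(path_of("trajectories.pdf"), width = 9, height = 4.5)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::par(mfrow = c(1, 2))
      for (ser in c("moving_mean", "std_variance")) {
        d <- curves[curves$series == ser, ]
        graphics::plot(NA, xlim = range(d$month), ylim = range(d$value),
                       xlab = "month since therapy start",
                       ylab = ser, main = paste("Typical", ser, "trajectories"))
        for (j in unique(d$class))
          graphics::lines(d$month[d$class == j], d$value[d$class == j],
                          col = j, lwd = 2)
        graphics::legend("bottomleft", legend = paste("class", unique(d$class)),
                         col = unique(d$class), lwd = 2, bty = "n")
      }
      outputs <<- c(outputs, "trajectories.pdf")
    }
  })

  manifest <- data.frame(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(config$outdir, outputs))))
  ## The PDF embeds a creation timestamp; exclude it from the content hash
  ## so manifests are comparable across reruns.
  manifest <- manifest[!grepl("\\.pdf$", manifest$file), , drop = FALSE]
  utils::write.csv(manifest, path_of("manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  log_msg("pipeline done in %.1fs (%d files)",
          as.numeric(difftime(Sys.time(), t0, units = "secs")),
          length(outputs))
  invisible(manifest)
}
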