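#' Write a cohort to delimited text files
#'
#' Writes `adherence.csv`, `visits.csv`, `survival.csv` and (optionally) the
#' ground-truth sidecar `truth.csv` into `dir`. All measurements are stored
#' at the precision the generator produces (adherence 2 decimals, CD4 one
#' decimal, viral load integer), so writing is byte-stable and
#' `read_cohort(write_cohort(x))` is an exact round trip.
#'
#' @param cohort a `sim_cohort` (or a list with the same data frames).
#' @param dir destination directory, created if needed.
#' @param truth write the ground-truth class table as well?
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(adherence = file.path(dir, "adherence.csv"),
             visits = file.path(dir, "visits.csv"),
             survival = file.path(dir, "survival.csv"))
  utils::write.csv(cohort$adherence, paths[["adherence"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$visits, paths[["visits"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$survival, paths[["survival"]], row.names = FALSE,
                   quote = FALSE)
  if (isTRUE(truth) && !is.null(cohort$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.csv"))
    utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE,
                     quote = FALSE)
  }
  invisible(paths)
}

#' Read a cohort from delimited text files
#'
#' Inverse of [write_cohort()]. Performs structural validation and names the
#' offending row on failure: non-numeric adherence values and duplicated
#' patient-month pairs are rejected.
#'
#' @param dir directory containing `adherence.csv`, `visits.csv`,
#'   `survival.csv` and optionally `truth.csv`.
#' @return object of class `sim_cohort` (without generator diagnostics).
#' @export
read_cohort <- function(dir) {
  need <- c("adherence.csv", "visits.csv", "survival.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f)))
      stop_cfg("missing cohort file: ", file.path(dir, f))
  }
  adherence <- read_checked(file.path(dir, "adherence.csv"),
                            c("patient_id", "month", "adherence"))
  visits <- read_checked(file.path(dir, "visits.csv"),
                         c("patient_id", "month", "cd4", "viral_load"))
  survival <- read_checked(file.path(dir, "survival.csv"),
                           c("patient_id", "time_month", "event"))
  dup <- duplicated(adherence[c("patient_id", "month")])
  if (any(dup))
    stop_cfg("adherence.csv: duplicated patient-month at row ", which(dup)[1L])
  if (nrow(adherence) &&
      any(adherence$adherence < 0 | adherence$adherence > 100))
    stop_cfg("adherence.csv: adherence outside [0, 100] at row ",
             which(adherence$adherence < 0 | adherence$adherence > 100)[1L])
  out <- list(adherence = adherence, visits = visits, survival = survival)
  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path))
    out$truth <- read_checked(truth_path,
                              c("patient_id", "true_mean_class", "true_var_class"))
  class(out) <- "sim_cohort"
  out
}

## Read a CSV whose non-id columns must parse as numbers; errors name the row.
read_checked <- function(path, cols) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), cols))
    stop_cfg(basename(path), ": expected columns ", paste(cols, collapse = ","),
             " but found ", paste(names(df), collapse = ","))
  for (cl in setdiff(cols, "patient_id")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & nzchar(df[[cl]]))
    if (length(bad))
      stop_cfg(basename(path), ": non-numeric '", cl, "' at row ", bad[1L],
               " (value '", df[[cl]][bad[1L]], "')")
    if (any(is.na(v)))
      stop_cfg(basename(path), ": missing '", cl, "' at row ", which(is.na(v))[1L])
    df[[cl]] <- if (cl %in% c("month", "time_month", "event",
                              "true_mean_class", "true_var_class"))
      as.integer(v) else v
  }
  df
}
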