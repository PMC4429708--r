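#' Cross-tabulation of mean-adherence and variability classes
#'
#' Builds the 3 x 3 (variance class x mean class) patient count table with
#' row and column percentages, in the layout used to report the joint
#' distribution of the two MAP classifications.
#'
#' @param assignments_mean data frame `patient_id`, `map_class` (1=cH,
#'   2=HsD, 3=DrI), e.g. from [map_classify()] on the mean-trajectory fit.
#' @param assignments_variance same for the variability classes (1=Low,
#'   2=Moderate, 3=High).
#' @return a `class_table` (see [class_table()]).
#' @export
cross_tabulate <- function(assignments_mean, assignments_variance) {
  a <- assignments_mean; b <- assignments_variance
  if (!setequal(a$patient_id, b$patient_id) ||
      anyDuplicated(a$patient_id) || anyDuplicated(b$patient_id)) {
    only_a <- setdiff(a$patient_id, b$patient_id)
    only_b <- setdiff(b$patient_id, a$patient_id)
    stop_cfg("mismatched patient sets; only in mean: {",
             paste(only_a, collapse = ","), "}, only in variance: {",
             paste(only_b, collapse = ","), "}")
  }
  m <- match(a$patient_id, b$patient_id)
  counts <- table(factor(var_class_labels()[b$map_class[m]],
                         levels = var_class_labels()),
                  factor(mean_class_labels()[a$map_class],
                         levels = mean_class_labels()))
  class_table(unclass(counts))
}

#' Percentage summaries of a class count table
#'
#' Computes, from a (variance x mean) class count matrix: row percentages
#' (cell / row total), column percentages (cell / column total), and the
#' marginal shares of each row and column in the grand total, all rounded
#' to 2 decimals.
#'
#' @param counts numeric matrix of patient counts (rows: variability
#'   classes, columns: mean-adherence classes).
#' @return object of class `class_table`: list with `counts`, `row_pct`,
#'   `col_pct`, `row_totals`, `col_totals`, `row_total_pct`,
#'   `col_total_pct` and `n`.
#' @export
class_table <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  row_tot <- rowSums(counts)
  col_tot <- colSums(counts)
  safe_div <- function(a, b) if (b > 0) a / b else a * 0
  structure(list(
    counts = counts,
    row_pct = round(100 * sweep(counts, 1L, pmax(row_tot, 1e-300), "/"), 2),
    col_pct = round(100 * sweep(counts, 2L, pmax(col_tot, 1e-300), "/"), 2),
    row_totals = row_tot, col_totals = col_tot,
    row_total_pct = round(100 * safe_div(row_tot, n), 2),
    col_total_pct = round(100 * safe_div(col_tot, n), 2),
    n = n), class = "class_table")
}

#' @export
print.class_table <- function(x, ...) {
  cat(sprintf("Class cross-tabulation (%d patients)\n", x$n))
  disp <- matrix(sprintf("%d (%.2f%%/%.2f%%)", x$counts, x$row_pct, x$col_pct),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(noquote(disp))
  cat("cell (row%/column%); row shares:",
      paste(sprintf("%.2f%%", x$row_total_pct), collapse = " "),
      "; column shares:",
      paste(sprintf("%.2f%%", x$col_total_pct), collapse = " "), "\n")
  invisible(x)
}

#' Flatten a class table to a data frame
#'
#' @param x a `class_table`.
#' @param ... unused.
#' @return data frame with one row per cell: `var_class`, `mean_class`,
#'   `count`, `row_pct`, `col_pct`.
#' @export
as.data.frame.class_table <- function(x, ...) {
  idx <- expand.grid(var_class = rownames(x$counts) %||%
                       paste0("r", seq_len(nrow(x$counts))),
                     mean_class = colnames(x$counts) %||%
                       paste0("c", seq_len(ncol(x$counts))),
                     stringsAsFactors = FALSE)
  data.frame(idx, count = as.vector(x$counts),
             row_pct = as.vector(x$row_pct),
             col_pct = as.vector(x$col_pct))
}

#' Published summary counts from the ANRS 1215 adherence cohort
#'
#' Machine-readable copies of published patient-level summary counts from
#' the Senegalese ISAARV / ANRS 1215 adherence cohort (317 analysable
#' patients): the 3 x 3 cross-classification of the variability strata
#' (Low/Moderate/High) against the mean-adherence trajectory classes
#' (cH/HsD/DrI), and the total number of deaths over follow-up. Useful for
#' exact re-computation of the derived percentages.
#'
#' @return list with `class_counts` (3 x 3 integer matrix, rows
#'   Low/Moderate/High, columns cH/HsD/DrI), `deaths` and `n_patients`.
#' @export
anrs1215_reference <- function() {
  counts <- matrix(c(40L, 20L, 11L,
                     127L, 14L, 14L,
                     54L, 20L, 17L),
                   nrow = 3L, byrow = TRUE,
                   dimnames = list(var_class_labels(), mean_class_labels()))
  list(class_counts = counts, deaths = 52L, n_patients = 317L)
}
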