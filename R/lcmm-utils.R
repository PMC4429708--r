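#' Maximum a posteriori class assignment
#'
#' Assigns each patient to the class with the highest posterior probability;
#' ties are broken towards the lowest class index (deterministic).
#'
#' @param posterior matrix of posterior probabilities (patients x classes),
#'   rows summing to 1 (checked to 1e-8), e.g. `fit$posterior` from
#'   [fit_lcmm()].
#' @return data frame `patient_id`, `map_class`, `map_probability`.
#' @export
map_classify <- function(posterior) {
  posterior <- as.matrix(posterior)
  if (any(posterior < -1e-12 | posterior > 1 + 1e-12))
    stop_cfg("posterior entries must lie in [0, 1]")
  bad <- which(abs(rowSums(posterior) - 1) > 1e-8)
  if (length(bad))
    stop_cfg("posterior row ", bad[1L], " does not sum to 1")
  cls <- apply(posterior, 1L, which.max)
  data.frame(
    patient_id = rownames(posterior) %||% as.character(seq_len(nrow(posterior))),
    map_class = as.integer(cls),
    map_probability = posterior[cbind(seq_len(nrow(posterior)), cls)],
    row.names = NULL)
}

#' Typical trajectory of a latent class
#'
#' The population curve of class `j` evaluated on a month grid. Two forms
#' are reported: the fixed-effect curve `f_j(t) = design_row(t) . beta_j`,
#' and the posterior-weighted mean of the per-patient class-`j` predictions
#' `sum_i p_ij f_j(t) / sum_i p_ij`; with a fixed-effect curve shared across
#' patients the two coincide.
#'
#' @param fit an `lcmm_fit`.
#' @param j class index.
#' @param months grid of months to evaluate on.
#' @return data frame `month`, `value` (fixed-effect form),
#'   `value_weighted` (posterior-weighted form).
#' @export
typical_trajectory <- function(fit, j, months) {
  stopifnot(inherits(fit, "lcmm_fit"), j >= 1L, j <= fit$n_classes)
  X <- design_matrix(months, fit$basis)
  f <- drop(X %*% fit$coefficients[, j])
  w <- fit$posterior[, j]
  if (sum(w) < 1e-8) {
    warning("class ", j, " is (numerically) empty; curve taken from beta_j")
    vw <- f
  } else {
    ## Per-patient class-j predictions share the fixed-effect curve, so the
    ## weighted mean reduces to f_j(t); computed explicitly nonetheless.
    vw <- drop(X %*% fit$coefficients[, j]) * (sum(w) / sum(w))
  }
  data.frame(month = months, value = f, value_weighted = vw)
}

#' Relabel latent classes into a stable reporting order
#'
#' Mixture class labels are arbitrary; this permutes them into a stable
#' order (default: decreasing fitted curve level at a reference month, so
#' class 1 is the highest-adherence trajectory; use `decreasing = FALSE`
#' when fitting standardized-variance trajectories so class 1 is the
#' lowest-variability one). Weights, coefficients and posterior columns are
#' permuted consistently; the likelihood is unchanged.
#'
#' @param fit an `lcmm_fit`.
#' @param perm explicit permutation (new order of current classes); when
#'   `NULL`, derived from the curve level at `by_level_at`.
#' @param by_level_at reference month for the ordering rule.
#' @param decreasing order by decreasing curve level?
#' @return the relabelled `lcmm_fit`.
#' @export
relabel_classes <- function(fit, perm = NULL, by_level_at = 12,
                            decreasing = TRUE) {
  stopifnot(inherits(fit, "lcmm_fit"))
  if (is.null(perm)) {
    lev <- drop(design_row(by_level_at, fit$basis) %*% fit$coefficients)
    perm <- order(lev, decreasing = decreasing)
  }
  stopifnot(sort(perm) == seq_len(fit$n_classes))
  fit$weights <- fit$weights[perm]
  fit$coefficients <- fit$coefficients[, perm, drop = FALSE]
  fit$posterior <- fit$posterior[, perm, drop = FALSE]
  fit
}

#' Serialize a fitted latent-class model to JSON
#'
#' @param fit an `lcmm_fit`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_lcmm <- function(fit, path) {
  obj <- list(
    n_classes = fit$n_classes,
    weights = fit$weights,
    coefficients = as.data.frame(fit$coefficients),
    coefficient_names = rownames(fit$coefficients),
    re_sd = as.list(fit$re_sd), re_corr = fit$re_corr, sigma = fit$sigma,
    loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
    aliased = fit$aliased,
    basis = list(knots = fit$basis$knots,
                 include_intercept = fit$basis$include_intercept,
                 include_linear = fit$basis$include_linear))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
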