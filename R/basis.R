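#' Linear-spline (hinge) time basis for trajectory curves
#'
#' The class mean curves are linear combinations of an intercept, a linear
#' time term and hinge functions `h_T(t) = max(0, t - T)` at a set of knots,
#' which lets each curve change slope (have inflexion points) at every knot.
#'
#' @param knots strictly increasing knot months, default
#'   `c(12, 24, 36, 48, 60, 72, 84, 96)`.
#' @param include_intercept,include_linear include the constant / linear
#'   time column?
#' @return object of class `basis_config`.
#' @export
basis_config <- function(knots = seq(12L, 96L, by = 12L),
                         include_intercept = TRUE,
                         include_linear = TRUE) {
  knots <- as.numeric(knots)
  if (length(knots) && is.unsorted(knots, strictly = TRUE))
    stop_cfg("knots must be strictly increasing")
  structure(list(knots = knots,
                 include_intercept = isTRUE(include_intercept),
                 include_linear = isTRUE(include_linear)),
            class = "basis_config")
}

#' Evaluate the basis at a single month
#'
#' @param t month since therapy start.
#' @param basis a [basis_config()].
#' @return numeric row `[1, t, max(0, t - T1), ..., max(0, t - Tk)]`
#'   (intercept/linear columns subject to the config flags).
#' @export
design_row <- function(t, basis = basis_config()) {
  stopifnot(length(t) == 1L, is.finite(t))
  c(if (basis$include_intercept) 1,
    if (basis$include_linear) t,
    pmax(0, t - basis$knots))
}

#' Design matrix of the basis over a vector of months
#'
#' @param t vector of months.
#' @param basis a [basis_config()].
#' @return matrix with one row per month and named columns.
#' @export
design_matrix <- function(t, basis = basis_config()) {
  cols <- c(if (basis$include_intercept) "(Intercept)",
            if (basis$include_linear) "t",
            if (length(basis$knots)) sprintf("h_%g", basis$knots))
  X <- t(vapply(t, design_row, numeric(length(cols)), basis = basis))
  colnames(X) <- cols
  X
}
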