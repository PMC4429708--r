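#' Fit a latent-class trajectory model by EM
#'
#' Fits a `J`-class finite mixture of linear mixed models to per-patient
#' longitudinal series. Conditionally on membership in class `j`, patient
#' `i`'s observations are Gaussian with mean `X_i beta_j` (the hinge-spline
#' basis of [basis_config()]) and covariance `V_i = Z_i D Z_i' + sigma^2 I`,
#' where `Z_i = [1, t]` carries a random intercept and a random slope on
#' time with free correlation; `D` and `sigma` are shared across classes.
#' The fitted criterion is the marginal mixture log-likelihood
#' `sum_i log sum_j pi_j phi(y_i; X_i beta_j, V_i)`.
#'
#' The E-step computes posterior class probabilities `p_ij` in closed form;
#' the M-step updates `pi` in closed form, profiles each `beta_j` by
#' weighted generalized least squares at any candidate variance parameters,
#' and improves `D` and `sigma` numerically (Nelder-Mead on a log/atanh
#' scale, started at the current values, so the expected complete-data
#' criterion — and hence the observed log-likelihood — never decreases).
#' After convergence the variance parameters are polished with a long
#' optimizer run; for `n_classes = 1` this makes the fit a plain
#' maximum-likelihood linear-mixed-model fit. The best of `n_starts` seeded
#' initializations (k-means on regularized per-patient OLS coefficients,
#' perturbed across starts) is returned.
#'
#' Columns of the pooled design matrix that are exactly collinear (for
#' instance `h_12` when every observation has `t >= 12`, where
#' `max(0, t - 12) = t - 12`) are detected by pivoted QR and dropped; their
#' coefficients are reported as 0 and listed in `$aliased`, leaving fitted
#' curves unchanged.
#'
#' @param data data frame with columns `patient_id`, `month`, `value`.
#' @param n_classes number of latent classes `J` (>= 1), default 3.
#' @param basis a [basis_config()].
#' @param n_starts number of seeded initializations, default 10.
#' @param seed integer seed for initialization randomness.
#' @param tol relative log-likelihood convergence tolerance, default 1e-6.
#' @param max_iter maximum EM iterations per start, default 500.
#' @param m_step_maxit Nelder-Mead iterations per M-step variance update.
#' @param sigma_floor lower bound on the residual SD, guarding against
#'   degenerate spikes.
#' @param verbose print per-start progress?
#' @return object of class `lcmm_fit` with elements `weights` (pi),
#'   `coefficients` (basis-by-class matrix), `re_sd` (random intercept and
#'   slope SDs), `re_corr`, `sigma`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `posterior` (patients-by-classes matrix with row names),
#'   `patient_ids`, `aliased`, `basis`, `n_classes`.
#' @export
fit_lcmm <- function(data, n_classes = 3L, basis = basis_config(),
                     n_starts = 10L, seed = 1L, tol = 1e-6,
                     max_iter = 500L, m_step_maxit = 10L,
                     sigma_floor = 1e-4, verbose = FALSE) {
  stopifnot(all(c("patient_id", "month", "value") %in% names(data)))
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) stop_cfg("n_classes must be >= 1")
  if (anyNA(data$value) || anyNA(data$month)) stop_cfg("NA in data")
  prep <- lcmm_prepare(data, basis)
  if (any(tabulate(prep$pat_index) == 0L))
    stop_cfg("every patient needs at least one observation")

  set.seed(as.integer(seed))
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  best <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- lcmm_init_posterior(prep, n_classes, start_seeds[s],
                              perturb = (s > 1L))
    fit <- lcmm_em(prep, n_classes, p0, tol = tol, max_iter = max_iter,
                   m_step_maxit = m_step_maxit, sigma_floor = sigma_floor)
    if (verbose)
      message(sprintf("start %d/%d: loglik %.4f after %d iterations",
                      s, n_starts, fit$loglik, fit$n_iter))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  structure(c(best, list(basis = basis, n_classes = n_classes,
                         patient_ids = prep$patients,
                         aliased = prep$aliased,
                         col_names = prep$col_names)),
            class = "lcmm_fit")
}

#' @export
print.lcmm_fit <- function(x, ...) {
  cat(sprintf("Latent-class trajectory model: %d classes, %d patients\n",
              x$n_classes, length(x$patient_ids)))
  cat(sprintf("  log-likelihood %.3f (%d EM iterations%s)\n", x$loglik,
              x$n_iter, if (x$converged) "" else ", NOT converged"))
  cat("  class weights:", sprintf("%.3f", x$weights), "\n")
  cat(sprintf("  random effects: sd(intercept) %.3f, sd(slope) %.4f, corr %.3f; sigma %.3f\n",
              x$re_sd[1], x$re_sd[2], x$re_corr, x$sigma))
  if (length(x$aliased))
    cat("  aliased basis columns (coefficient fixed at 0):",
        paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

## ---- internal machinery ---------------------------------------------------

## Group patients by identical observation-time pattern so the per-group
## covariance factorization is shared.
lcmm_prepare <- function(data, basis) {
  data <- data[order(match(data$patient_id, unique(data$patient_id)),
                     data$month), , drop = FALSE]
  patients <- unique(data$patient_id)
  pat_index <- match(data$patient_id, patients)

  X_all <- design_matrix(data$month, basis)
  qrX <- qr(X_all)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  aliased <- colnames(X_all)[setdiff(seq_len(ncol(X_all)), keep)]

  sig <- vapply(split(data$month, pat_index), paste, "", collapse = ",")
  grp_of_patient <- match(sig, unique(sig))
  groups <- lapply(seq_along(unique(sig)), function(g) {
    pats <- which(grp_of_patient == g)
    rows_first <- which(pat_index == pats[1L])
    t_g <- data$month[rows_first]
    Y <- vapply(pats, function(p) data$value[pat_index == p],
                numeric(length(t_g)))
    Y <- matrix(Y, nrow = length(t_g))
    list(t = t_g, X = X_all[rows_first, keep, drop = FALSE],
         Z = cbind(1, t_g), Y = Y, pats = pats, n_t = length(t_g))
  })
  list(groups = groups, patients = patients, pat_index = pat_index,
       n_patients = length(patients), keep = keep, aliased = aliased,
       col_names = colnames(X_all), p = length(keep), data = data)
}

lcmm_theta_unpack <- function(par, sigma_floor) {
  s0 <- exp(par[1L]); s1 <- exp(par[2L]); rho <- tanh(par[3L])
  sigma <- sigma_floor + exp(par[4L])
  D <- matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2L, 2L)
  list(D = D, sigma = sigma, s0 = s0, s1 = s1, rho = rho)
}

## Cholesky-based per-group quantities for given variance parameters.
lcmm_group_mats <- function(prep, theta) {
  lapply(prep$groups, function(g) {
    V <- g$Z %*% theta$D %*% t(g$Z) + diag(theta$sigma^2, g$n_t)
    C <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    Xt <- backsolve(C, g$X, transpose = TRUE)
    Yt <- backsolve(C, g$Y, transpose = TRUE)
    list(Xt = Xt, Yt = Yt, A = crossprod(Xt),
         logdet = 2 * sum(log(diag(C))), n_t = g$n_t, pats = g$pats)
  })
}

## Profile betas by weighted GLS and evaluate the weighted complete-data
## Gaussian criterion Q = sum_ij p_ij log phi_ij at those betas.
lcmm_Q <- function(par, prep, p_mat, sigma_floor) {
  theta <- lcmm_theta_unpack(par, sigma_floor)
  mats <- lcmm_group_mats(prep, theta)
  if (any(vapply(mats, is.null, logical(1)))) return(list(Q = -Inf))
  J <- ncol(p_mat)
  pdim <- prep$p
  beta <- matrix(0, pdim, J)
  for (j in seq_len(J)) {
    M <- matrix(0, pdim, pdim); b <- numeric(pdim)
    for (g in mats) {
      w <- p_mat[g$pats, j]
      M <- M + sum(w) * g$A
      b <- b + crossprod(g$Xt, g$Yt %*% w)
    }
    beta[, j] <- tryCatch(
      solve(M + diag(1e-10 * max(diag(M), 1), pdim), b),
      error = function(e) rep(0, pdim))
  }
  Q <- 0
  for (g in mats) {
    const <- -0.5 * (g$n_t * log(2 * pi) + g$logdet)
    for (j in seq_len(J)) {
      Rt <- g$Yt - drop(g$Xt %*% beta[, j])
      q_i <- colSums(Rt^2)
      Q <- Q + sum(p_mat[g$pats, j] * (const - 0.5 * q_i))
    }
  }
  list(Q = Q, beta = beta, theta = theta, mats = mats)
}

## Per-patient class-conditional log-densities at given beta/theta.
lcmm_logdens <- function(prep, mats, beta) {
  J <- ncol(beta)
  L <- matrix(NA_real_, prep$n_patients, J)
  for (g in mats) {
    const <- -0.5 * (g$n_t * log(2 * pi) + g$logdet)
    for (j in seq_len(J)) {
      Rt <- g$Yt - drop(g$Xt %*% beta[, j])
      L[g$pats, j] <- const - 0.5 * colSums(Rt^2)
    }
  }
  L
}

lcmm_estep <- function(prep, mats, beta, weights) {
  L <- lcmm_logdens(prep, mats, beta)
  A <- sweep(L, 2L, log(weights), "+")
  lse <- log_row_sum_exp(A)
  list(loglik = sum(lse), p = exp(A - lse))
}

lcmm_init_theta <- function(prep) {
  y <- prep$data$value
  s <- stats::sd(y)
  if (!is.finite(s) || s <= 0) s <- 1
  c(log(s / 2), log(max(s / 200, 1e-3)), 0, log(s / 2))
}

## Initial posterior from k-means on regularized per-patient OLS
## coefficients of the same basis.
lcmm_init_posterior <- function(prep, J, seed, perturb = FALSE) {
  n <- prep$n_patients
  if (J == 1L) return(matrix(1, n, 1L))
  feats <- matrix(0, n, prep$p)
  for (g in prep$groups) {
    A <- crossprod(g$X) + diag(1e-6 * max(1, sum(g$X^2)), prep$p)
    B <- solve(A, crossprod(g$X, g$Y))
    feats[g$pats, ] <- t(B)
  }
  sds <- apply(feats, 2L, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  feats <- sweep(feats, 2L, sds, "/")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  if (perturb) feats <- feats + matrix(stats::rnorm(length(feats), 0, 0.25),
                                       nrow = n)
  km <- tryCatch(stats::kmeans(feats, centers = min(J, n), nstart = 3L),
                 error = function(e) NULL)
  cl <- if (is.null(km)) sample.int(J, n, replace = TRUE) else km$cluster
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  p <- matrix(0.1 / max(1, J - 1), n, J)
  p[cbind(seq_len(n), ((cl - 1L) %% J) + 1L)] <- 0.9
  p / rowSums(p)
}

lcmm_em <- function(prep, J, p_mat, tol, max_iter, m_step_maxit,
                    sigma_floor) {
  par <- lcmm_init_theta(prep)
  loglik_trace <- numeric(0)
  loglik <- -Inf
  converged <- FALSE
  q_now <- lcmm_Q(par, prep, p_mat, sigma_floor)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## M-step: weights in closed form, variance parameters by a bounded
    ## Nelder-Mead improvement of Q (generalized EM), betas profiled.
    weights <- pmax(colMeans(p_mat), 1e-8)
    weights <- weights / sum(weights)
    opt <- stats::optim(par, function(th) {
      q <- lcmm_Q(th, prep, p_mat, sigma_floor)$Q
      if (!is.finite(q)) 1e12 else -q
    }, method = "Nelder-Mead", control = list(maxit = m_step_maxit))
    if (-opt$value >= q_now$Q) par <- opt$par
    q_now <- lcmm_Q(par, prep, p_mat, sigma_floor)
    ## E-step.
    e <- lcmm_estep(prep, q_now$mats, q_now$beta, weights)
    p_mat <- e$p
    loglik_trace <- c(loglik_trace, e$loglik)
    if (is.finite(loglik) &&
        abs(e$loglik - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- e$loglik
      converged <- TRUE
      break
    }
    loglik <- e$loglik
  }
  ## Final polish of the variance parameters (full M-step), then a last
  ## E-step so the returned posterior matches the returned parameters.
  weights <- pmax(colMeans(p_mat), 1e-8); weights <- weights / sum(weights)
  negQ <- function(th) {
    q <- lcmm_Q(th, prep, p_mat, sigma_floor)$Q
    if (!is.finite(q)) 1e12 else -q
  }
  opt <- stats::optim(par, negQ, method = "Nelder-Mead",
                      control = list(maxit = 2000L, reltol = 1e-12))
  if (-opt$value >= q_now$Q) par <- opt$par
  opt2 <- tryCatch(
    stats::optim(par, negQ, method = "BFGS",
                 control = list(maxit = 200L, reltol = 1e-14)),
    error = function(e) NULL)
  if (!is.null(opt2) && opt2$value <= opt$value) par <- opt2$par
  q_now <- lcmm_Q(par, prep, p_mat, sigma_floor)
  e <- lcmm_estep(prep, q_now$mats, q_now$beta, weights)
  loglik_trace <- c(loglik_trace, e$loglik)

  theta <- q_now$theta
  coef_full <- matrix(0, length(prep$col_names), J,
                      dimnames = list(prep$col_names, NULL))
  coef_full[prep$keep, ] <- q_now$beta
  posterior <- e$p
  rownames(posterior) <- as.character(prep$patients)
  list(weights = weights, coefficients = coef_full,
       re_sd = c(intercept = theta$s0, slope = theta$s1),
       re_corr = theta$rho, sigma = theta$sigma,
       loglik = e$loglik, loglik_trace = loglik_trace,
       n_iter = iter, converged = converged, posterior = posterior)
}

#' Marginal mixture log-likelihood of a fitted model on data
#'
#' Recomputes `sum_i log sum_j pi_j phi(y_i; X_i beta_j, V_i)` for a fitted
#' model on (possibly new) data with the same column layout.
#'
#' @param fit an `lcmm_fit`.
#' @param data data frame with `patient_id`, `month`, `value`.
#' @return the log-likelihood (scalar).
#' @export
lcmm_loglik <- function(fit, data) {
  prep <- lcmm_prepare(data, fit$basis)
  theta <- list(D = lcmm_re_cov(fit), sigma = fit$sigma)
  mats <- lcmm_group_mats(prep, theta)
  beta <- fit$coefficients[prep$keep, , drop = FALSE]
  L <- lcmm_logdens(prep, mats, beta)
  sum(log_row_sum_exp(sweep(L, 2L, log(fit$weights), "+")))
}

lcmm_re_cov <- function(fit) {
  s0 <- fit$re_sd[[1L]]; s1 <- fit$re_sd[[2L]]; rho <- fit$re_corr
  matrix(c(s0^2, rho * s0 * s1, rho * s0 * s1, s1^2), 2L, 2L)
}
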