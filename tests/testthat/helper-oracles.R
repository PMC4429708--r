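# Independent brute-force oracles and small fixtures used across tests.

## Moving statistics by direct windowed computation.
oracle_moving <- function(months, values, window = 12) {
  full <- rep(NA_real_, max(months))
  full[months] <- values
  out <- NULL
  for (t in seq(window, length(full))) {
    w <- full[(t - window + 1):t]
    if (!anyNA(w))
      out <- rbind(out, data.frame(month = t, moving_mean = mean(w),
                                   moving_variance = stats::var(w)))
  }
  out
}

## Standardization by explicit sort / partition / count-based ranking.
oracle_standardize <- function(moving_mean, moving_variance, target = 30) {
  N <- length(moving_mean)
  ord <- order(moving_mean)
  K <- max(1, round(N / target))
  base <- N %/% K
  sizes <- rep(base, K)
  r <- N - base * K
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  z <- numeric(N)
  pos <- 1
  for (c_i in seq_len(K)) {
    idx <- ord[pos:(pos + sizes[c_i] - 1)]
    v <- moving_variance[idx]
    ## average rank by counting: (# strictly below) + (1 + # tied) / 2
    rk <- vapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2,
                 numeric(1))
    z[idx] <- qnorm(rk / (1 + sizes[c_i]))
    pos <- pos + sizes[c_i]
  }
  z
}

## Marginal mixture log-likelihood by direct multivariate-normal density
## summation (determinant + solve; no Cholesky sharing with the fitter).
oracle_mixture_loglik <- function(data, basis, weights, coef_full, D, sigma) {
  total <- 0
  for (pid in unique(data$patient_id)) {
    d <- data[data$patient_id == pid, ]
    d <- d[order(d$month), ]
    X <- design_matrix(d$month, basis)
    Z <- cbind(1, d$month)
    V <- Z %*% D %*% t(Z) + diag(sigma^2, nrow(d))
    dens <- vapply(seq_along(weights), function(j) {
      r <- d$value - drop(X %*% coef_full[, j])
      logdet <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
      exp(-0.5 * (nrow(d) * log(2 * pi) + logdet +
                    drop(crossprod(r, solve(V, r)))))
    }, numeric(1))
    total <- total + log(sum(weights * dens))
  }
  total
}

## Cox log partial likelihood for episode data, evaluated directly.
oracle_cox_logpl <- function(beta, episodes, xcol) {
  ev <- episodes[episodes$event == 1, ]
  ll <- 0
  for (k in seq_len(nrow(ev))) {
    tstop <- ev$stop[k]
    risk <- episodes$start < tstop & episodes$stop >= tstop
    ll <- ll + beta * ev[[xcol]][k] -
      log(sum(exp(beta * episodes[[xcol]][risk])))
  }
  ll
}

## Logistic regression by direct likelihood optimization (oracle for the
## single-period degenerate case of the mixed logistic model).
oracle_logistic <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(rep(0, ncol(X)), nll, method = "BFGS",
        control = list(maxit = 1000, reltol = 1e-14))$par
}

## Small well-separated cohort configuration used by recovery tests.
separated_config <- function(n = 120, seed = 1, noise = c(3, 3.5, 4), ...) {
  cohort_config(n_patients = n, seed = seed,
                noise_sd_by_var_class = noise, ...)
}

## Per-patient long data frame of moving means for trajectory fitting.
moving_value_data <- function(cohort, what = "moving_mean", window = 12) {
  mv <- moving_mean_variance(cohort$adherence, window = window)
  if (what == "std_variance")
    mv <- standardize_variances(mv)$points
  data.frame(patient_id = mv$patient_id, month = mv$month, value = mv[[what]])
}
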