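#' Moving mean and variance of monthly adherence
#'
#' Starting from the month at which a full window is first available,
#' computes for every patient-month the mean and the sample variance
#' (denominator n - 1) of the adherence values over the previous `window`
#' months (months `t - window + 1` .. `t`). By default a value is emitted
#' only when all `window` months in the window are observed
#' (`min_months = window`); lowering `min_months` allows windows with at
#' least that many observed months.
#'
#' @param adherence data frame with columns `patient_id`, `month` (positive
#'   integers) and `adherence` (0-100).
#' @param window window length in months (>= 2), default 12.
#' @param min_months minimum observed months for a window to be emitted.
#' @return data frame `patient_id`, `month`, `moving_mean`,
#'   `moving_variance`, in ascending month within patient.
#' @export
moving_mean_variance <- function(adherence, window = 12L,
                                 min_months = window) {
  window <- as.integer(window)
  if (window < 2L) stop_cfg("window must be >= 2 months")
  min_months <- as.integer(min_months)
  if (min_months < 2L || min_months > window)
    stop_cfg("min_months must be in [2, window]")
  req <- c("patient_id", "month", "adherence")
  if (!all(req %in% names(adherence)))
    stop_cfg("adherence must have columns ", paste(req, collapse = ", "))
  if (nrow(adherence) == 0L)
    return(data.frame(patient_id = character(), month = integer(),
                      moving_mean = numeric(), moving_variance = numeric()))
  if (any(adherence$month < 1L | adherence$month != floor(adherence$month)))
    stop_cfg("months must be positive integers")
  if (anyDuplicated(adherence[c("patient_id", "month")]))
    stop_cfg("duplicate patient-month in adherence data")

  pieces <- lapply(split(adherence, adherence$patient_id), function(d) {
    Mx <- max(d$month)
    if (Mx < window) return(NULL)
    y <- rep(NA_real_, Mx)
    y[d$month] <- d$adherence
    obs <- !is.na(y)
    y0 <- ifelse(obs, y, 0)
    cs <- c(0, cumsum(y0)); cs2 <- c(0, cumsum(y0^2)); cn <- c(0L, cumsum(obs))
    t_end <- seq(window, Mx)
    lo <- t_end - window
    n_w <- cn[t_end + 1L] - cn[lo + 1L]
    s_w <- cs[t_end + 1L] - cs[lo + 1L]
    s2_w <- cs2[t_end + 1L] - cs2[lo + 1L]
    ok <- n_w >= min_months
    if (!any(ok)) return(NULL)
    n_w <- n_w[ok]; s_w <- s_w[ok]; s2_w <- s2_w[ok]
    mm <- s_w / n_w
    mv <- pmax(0, (s2_w - n_w * mm^2) / (n_w - 1))
    data.frame(patient_id = d$patient_id[1L], month = t_end[ok],
               moving_mean = mm, moving_variance = mv)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    return(data.frame(patient_id = character(), month = integer(),
                      moving_mean = numeric(), moving_variance = numeric()))
  out <- out[order(out$patient_id, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-based normal-quantile standardization of moving variances
#'
#' The moving variance is strongly (negatively) linked to the moving mean;
#' this transform produces a variance measure decorrelated from the mean.
#' All pooled patient-month pairs are sorted by increasing moving mean
#' (stable on ties) and partitioned into `K = max(1, round(N /
#' target_class_size))` consecutive small-amplitude classes of near-equal
#' size (the remainder spread one per class from the first class). Within a
#' class of size `n_c`, the variance with rank `k` (average ranks on ties)
#' maps to `z = qnorm(k / (1 + n_c))`: the within-class empirical
#' distribution function of the variances is matched to standard-normal
#' quantiles.
#'
#' @param points data frame containing `moving_mean` and `moving_variance`
#'   (additional columns are carried through).
#' @param target_class_size intended class size, default 30.
#' @return list with `points` (input plus `std_variance` and `std_class`)
#'   and `map`, a `std_map` holding the class mean-intervals, sizes and
#'   sorted training variances for re-use on held-out points via
#'   [apply_std_map()].
#' @export
standardize_variances <- function(points, target_class_size = 30L) {
  if (!all(c("moving_mean", "moving_variance") %in% names(points)))
    stop_cfg("points must contain moving_mean and moving_variance")
  N <- nrow(points)
  if (N < 2L) stop_cfg("at least 2 pooled points are required")
  if (anyNA(points$moving_mean) || anyNA(points$moving_variance))
    stop_cfg("NA moving_mean/moving_variance in pooled points")

  ord <- order(points$moving_mean)  # stable
  K <- max(1L, as.integer(round(N / target_class_size)))
  base <- N %/% K
  sizes <- rep.int(base, K)
  r <- N - base * K
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  cls_sorted <- rep.int(seq_len(K), times = sizes)

  std_class <- integer(N)
  std_class[ord] <- cls_sorted
  z <- numeric(N)
  mean_lo <- numeric(K); mean_hi <- numeric(K)
  train_var <- vector("list", K)
  for (c_i in seq_len(K)) {
    idx <- ord[cls_sorted == c_i]
    n_c <- length(idx)
    rk <- rank(points$moving_variance[idx], ties.method = "average")
    z[idx] <- stats::qnorm(rk / (1 + n_c))
    mean_lo[c_i] <- points$moving_mean[idx[1L]]
    mean_hi[c_i] <- points$moving_mean[idx[n_c]]
    train_var[[c_i]] <- sort(points$moving_variance[idx])
  }
  map <- structure(list(K = K, sizes = sizes, mean_lo = mean_lo,
                        mean_hi = mean_hi, train_var = train_var,
                        target_class_size = as.integer(target_class_size)),
                   class = "std_map")
  points$std_variance <- z
  points$std_class <- std_class
  list(points = points, map = map)
}

#' Apply a fitted standardization map to held-out points
#'
#' Assigns each new point, by its moving mean, to the training class whose
#' mean interval contains it (or the nearest boundary class when it falls
#' outside all intervals), then converts its moving variance to a normal
#' quantile through that class's empirical distribution function:
#' `z = qnorm(k / (1 + n_c))` with `k` the number of training variances at
#' or below the new value (at least 1/2 so the result stays finite).
#'
#' @param map a `std_map` from [standardize_variances()].
#' @param points data frame with `moving_mean` and `moving_variance`.
#' @return `points` with `std_variance` and `std_class` columns added.
#' @export
apply_std_map <- function(map, points) {
  stopifnot(inherits(map, "std_map"))
  mids <- (map$mean_lo + map$mean_hi) / 2
  cls <- vapply(points$moving_mean, function(m) {
    inside <- which(map$mean_lo <= m & m <= map$mean_hi)
    if (length(inside)) return(inside[1L])
    which.min(pmin(abs(m - map$mean_lo), abs(m - map$mean_hi)))
  }, integer(1))
  z <- vapply(seq_len(nrow(points)), function(i) {
    tv <- map$train_var[[cls[i]]]
    n_c <- length(tv)
    k <- max(0.5, sum(tv <= points$moving_variance[i]))
    stats::qnorm(k / (1 + n_c))
  }, numeric(1))
  points$std_variance <- z
  points$std_class <- cls
  points
}

#' @export
print.std_map <- function(x, ...) {
  cat(sprintf("Variance standardization map: %d classes (target size %d)\n",
              x$K, x$target_class_size))
  cat(sprintf("  class sizes %d-%d; mean range [%.2f, %.2f]\n",
              min(x$sizes), max(x$sizes), min(x$mean_lo), max(x$mean_hi)))
  invisible(x)
}

#' Serialize / deserialize a standardization map as JSON
#'
#' @param map a `std_map`.
#' @param path file path for the JSON representation.
#' @return `write_std_map` returns `path` invisibly; `read_std_map` the map.
#' @export
write_std_map <- function(map, path) {
  ## 17 significant digits make the decimal serialization exact for doubles
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_std_map
#' @export
read_std_map <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tv <- raw$train_var
  ## equal-sized classes simplify to a matrix (one class per row)
  if (is.matrix(tv)) tv <- lapply(seq_len(nrow(tv)), function(i) tv[i, ])
  structure(list(K = as.integer(raw$K), sizes = as.integer(raw$sizes),
                 mean_lo = as.numeric(raw$mean_lo),
                 mean_hi = as.numeric(raw$mean_hi),
                 train_var = lapply(tv, as.numeric),
                 target_class_size = as.integer(raw$target_class_size)),
            class = "std_map")
}
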