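# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Row-wise log-sum-exp, guarded against -Inf rows.
log_row_sum_exp <- function(L) {
  m <- apply(L, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(L - m)))
}

stop_cfg <- function(...) stop(..., call. = FALSE)

## --- Splittable RNG -------------------------------------------------------
## All generator randomness flows through L'Ecuyer-CMRG streams: one stream
## per patient (advanced with parallel::nextRNGStream) plus a cohort-level
## stream, so earlier patients' draws are unchanged when n_patients grows.

rng_root_state <- function(seed) {
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "L'Ecuyer-CMRG")
  get(".Random.seed", globalenv())
}

rng_streams <- function(seed, n) {
  s <- rng_root_state(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  out
}

## Evaluate expr with .Random.seed set to `state`; restores the caller's RNG.
with_rng_state <- function(state, expr) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  assign(".Random.seed", state, globalenv())
  expr
}

## Best label permutation (maximum agreement) between two integer labelings.
## Small J only; used to align estimated mixture classes with ground truth.
#' Align estimated class labels with reference labels
#'
#' Finds the permutation of estimated class labels that maximizes agreement
#' with a reference labeling (mixture-model labels are identified only up to
#' permutation).
#'
#' @param estimated integer vector of estimated classes (1..J).
#' @param reference integer vector of reference classes, same length.
#' @return list with `perm` (index: new label of estimated class j),
#'   `relabelled` (the permuted estimated labels) and `agreement`
#'   (proportion matching the reference).
#' @export
align_class_labels <- function(estimated, reference) {
  stopifnot(length(estimated) == length(reference))
  J <- max(estimated, reference)
  perms <- all_permutations(J)
  best <- NULL
  best_agree <- -1
  for (p in perms) {
    rel <- p[estimated]
    agree <- mean(rel == reference)
    if (agree > best_agree) {
      best_agree <- agree
      best <- p
    }
  }
  list(perm = best, relabelled = best[estimated], agreement = best_agree)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  }
  out
}
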