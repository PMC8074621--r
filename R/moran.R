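# Global and local Moran's I with permutation pseudo p-values. Weights are
# binary and NOT row-standardized (a row-standardized variant is available
# behind `row_standardize`), matching the double-sum form
#   I = (m / S0) * sum_{j,l} w_{j,l} (p_j - pbar)(p_l - pbar) / sum_j (p_j - pbar)^2
# with S0 the sum of all weights.

.check_moran_input <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (length(values) != weights$n) stop("values length does not match weights units")
  if (any(!is.finite(values))) stop("values must be finite")
  if (stats::var(values) == 0) stop("zero variance: Moran's I undefined for constant values")
  if (nrow(weights$edges) == 0) stop("all-zero weights matrix")
}

.pseudo_p <- function(obs, perm, alternative) {
  B <- length(perm)
  switch(alternative,
    greater = (1 + sum(perm >= obs)) / (1 + B),
    less = (1 + sum(perm <= obs)) / (1 + B),
    two.sided = min(1, 2 * min((1 + sum(perm >= obs)) / (1 + B),
                               (1 + sum(perm <= obs)) / (1 + B))))
}

#' Global Moran's I with permutation inference
#'
#' Pseudo p-values come from `n_perm` random relabelings of the values over
#' the units, upper-tailed by default (the clustering alternative), with
#' the add-one convention so p is never 0.
#'
#' @param values Numeric vector, one value per unit.
#' @param weights A "spatial_weights" object over the same units.
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @param alternative "greater" (default), "less" or "two.sided".
#' @param row_standardize Row-standardize the weights before computing
#'   (default FALSE: binary weights).
#' @return list of class "moran_result": statistic, expectation -1/(m-1),
#'   pseudo_p, n_permutations, seed, alternative.
#' @export
global_moran <- function(values, weights, n_perm = 999, seed = 1L,
                         alternative = c("greater", "less", "two.sided"),
                         row_standardize = FALSE) {
  alternative <- match.arg(alternative)
  .check_moran_input(values, weights)
  m <- weights$n
  W <- weights_matrix(weights)
  if (row_standardize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  S0 <- sum(W)
  stat_fun <- function(z) {
    (m / S0) * as.numeric(Matrix::crossprod(z, W %*% z)) / sum(z^2)
  }
  z <- values - mean(values)
  obs <- stat_fun(z)
  perm <- numeric(0)
  if (n_perm > 0) {
    with_local_seed(seed, {
      Z <- vapply(seq_len(n_perm), function(b) z[sample.int(m)], numeric(m))
      perm <- (m / S0) * Matrix::colSums(Z * (W %*% Z)) / sum(z^2)
    })
  }
  structure(list(statistic = obs, expectation = -1 / (m - 1),
                 pseudo_p = if (n_perm > 0) .pseudo_p(obs, perm, alternative) else NA_real_,
                 permutations = perm, n_permutations = n_perm, seed = seed,
                 alternative = alternative, type = "global"),
            class = "moran_result")
}

#' Local Moran's I with conditional permutation inference
#'
#' Implements the (m-1)-prefactor variant
#'   I_j = (m-1) (p_j - pbar) / sum_{l != j} (p_l - pbar)^2 *
#'         sum_{l != j} w_{j,l} (p_l - pbar).
#' Per-unit pseudo p-values use conditional permutation: unit j's value is
#' held fixed and its neighbours' values are drawn from the remaining
#' units. Units without neighbours get I_j = 0 and p = NA.
#'
#' @inheritParams global_moran
#' @return list of class "moran_result" with vector `statistic` and
#'   `pseudo_p`.
#' @export
local_moran <- function(values, weights, n_perm = 999, seed = 1L,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  .check_moran_input(values, weights)
  m <- weights$n
  z <- values - mean(values)
  nbrs <- split(weights$edges$to, factor(weights$edges$from, levels = seq_len(m)))
  ssq <- sum(z^2)
  obs <- numeric(m); pp <- rep(NA_real_, m)
  with_local_seed(seed, {
    for (j in seq_len(m)) {
      nb <- nbrs[[j]]
      if (length(nb) == 0) { obs[j] <- 0; next }
      obs[j] <- (m - 1) * z[j] / (ssq - z[j]^2) * sum(z[nb])
      if (n_perm > 0) {
        pool <- z[-j]
        perm <- vapply(seq_len(n_perm), function(b) {
          sum(pool[sample.int(m - 1, length(nb))])
        }, numeric(1))
        perm <- (m - 1) * z[j] / (ssq - z[j]^2) * perm
        pp[j] <- .pseudo_p(obs[j], perm, alternative)
      }
    }
  })
  structure(list(statistic = obs, pseudo_p = pp, n_permutations = n_perm,
                 seed = seed, alternative = alternative, type = "local"),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  if (x$type == "global") {
    cat(sprintf("Global Moran's I = %.6f (E[I] = %.6f), pseudo p = %s (%d permutations, %s)\n",
                x$statistic, x$expectation,
                format(x$pseudo_p), x$n_permutations, x$alternative))
  } else {
    cat(sprintf("Local Moran's I over %d units; %d with pseudo p < 0.05 (%d permutations)\n",
                length(x$statistic), sum(x$pseudo_p < 0.05, na.rm = TRUE),
                x$n_permutations))
  }
  invisible(x)
}
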