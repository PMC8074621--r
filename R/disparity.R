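# Spatial disparity of district median delays: permutation envelope over
# ranked medians, and one-sided Gini / inter-decile-range permutation tests.
# The permutation null randomly reassigns events to districts while keeping
# every district's event count fixed (equivalently: shuffling delays over
# fixed district slots).

#' Permute district assignments
#'
#' Returns a relabeling of events to districts drawn uniformly among those
#' preserving every district's event count.
#'
#' @param district_id Vector of district labels, one per event.
#' @return Permuted label vector (same multiset).
#' @export
permute_assignments <- function(district_id) {
  if (length(unique(district_id)) < 2) {
    warning("single district: permutation is the identity")
    return(district_id)
  }
  district_id[sample.int(length(district_id))]
}

.district_medians <- function(delay, grp) {
  as.numeric(tapply(delay, grp, stats::median))
}

#' Gini coefficient
#'
#' Population (biased) form `G = sum_{a,b} |v_a - v_b| / (2 n^2 vbar)`,
#' computed via the sorted-values identity; scale-invariant, 0 for perfect
#' equality.
#'
#' @param values Nonnegative numeric vector, not all zero.
#' @return Gini coefficient in [0, 1).
#' @export
gini <- function(values) {
  if (any(values < 0)) stop("gini requires nonnegative values")
  if (all(values == 0)) stop("gini undefined for all-zero values")
  n <- length(values)
  v <- sort(values)
  2 * sum(seq_len(n) * v) / (n * sum(v)) - (n + 1) / n
}

#' Inter-decile range
#'
#' 90th minus 10th percentile under the linear-interpolation quantile rule
#' (R type 7).
#'
#' @param values Numeric vector of length >= 10.
#' @return Nonnegative scalar.
#' @export
interdecile_range <- function(values) {
  if (length(values) < 10) stop("interdecile_range needs at least 10 values")
  q <- stats::quantile(values, c(0.1, 0.9), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Ranked-median permutation envelope
#'
#' For each of `n_perm` random reassignments of events to districts (event
#' counts fixed), district median delays are computed and sorted; per rank
#' the null mean and 2.5/97.5 percentile bounds are reported and observed
#' ranked medians falling outside their rank's interval are flagged.
#' Districts without events are excluded.
#'
#' @param events data.frame with `delay_days` and `district_id`.
#' @param n_perm Number of permutations (warning below 100).
#' @param seed Integer seed.
#' @param level Envelope coverage (default 0.95).
#' @return list of class "disparity_envelope": per-rank table (observed,
#'   null_mean, lower, upper, outside) plus n_perm and seed.
#' @export
ranked_median_envelope <- function(events, n_perm = 1000, seed = 1L, level = 0.95) {
  if (n_perm < 100) warning("fewer than 100 permutations: envelope is unstable")
  grp <- factor(events$district_id)
  grp <- droplevels(grp)
  obs <- sort(.district_medians(events$delay_days, grp))
  m <- length(obs)
  a <- (1 - level) / 2
  with_local_seed(seed, {
    perm <- matrix(0, n_perm, m)
    delay <- events$delay_days
    for (b in seq_len(n_perm)) {
      perm[b, ] <- sort(.district_medians(delay[sample.int(length(delay))], grp))
    }
    tab <- data.frame(
      rank = seq_len(m),
      observed = obs,
      null_mean = colMeans(perm),
      lower = apply(perm, 2, stats::quantile, probs = a, type = 7),
      upper = apply(perm, 2, stats::quantile, probs = 1 - a, type = 7)
    )
    tab$outside <- tab$observed < tab$lower | tab$observed > tab$upper
    structure(list(table = tab, n_permutations = n_perm, seed = seed, level = level),
              class = "disparity_envelope")
  })
}

#' One-sided disparity permutation test
#'
#' Tests whether district median delays are more dispersed (Gini or
#' inter-decile range) than expected under random spatial assignment of
#' events to districts with fixed counts. Upper one-sided, add-one p.
#'
#' @param events data.frame with `delay_days` and `district_id`.
#' @param statistic "gini" or "idr".
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return list: observed, p_value, n_permutations, statistic, seed.
#' @export
disparity_test <- function(events, statistic = c("gini", "idr"),
                           n_perm = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  stat_fun <- if (statistic == "gini") gini else interdecile_range
  grp <- droplevels(factor(events$district_id))
  delay <- events$delay_days
  obs <- stat_fun(.district_medians(delay, grp))
  with_local_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) {
      stat_fun(.district_medians(delay[sample.int(length(delay))], grp))
    }, numeric(1))
    list(observed = obs,
         p_value = (1 + sum(perm >= obs)) / (1 + n_perm),
         n_permutations = n_perm, statistic = statistic, seed = seed)
  })
}
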