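# Model diagnostics: residual spatial autocorrelation (RSA), significant
# coefficients from an unpenalized refit on the L1-selected support, and
# permutation feature importance.

#' Residual spatial autocorrelation test
#'
#' Global Moran's I permutation test on pooled out-of-sample residuals
#' (observed minus predicted value for regression, observed label minus
#' predicted probability for classification) under the supplied weights.
#' A non-significant result indicates the model absorbed the spatial
#' signal.
#'
#' @param residuals Numeric residual vector aligned with the weights units.
#' @param weights A "spatial_weights" object over the events.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative Tail (default "greater": positive autocorrelation).
#' @return list: statistic, pseudo_p, n_permutations, scheme.
#' @export
rsa_test <- function(residuals, weights, n_perm = 999, seed = 1L,
                     alternative = "greater") {
  res <- global_moran(residuals, weights, n_perm = n_perm, seed = seed,
                      alternative = alternative)
  list(statistic = res$statistic, pseudo_p = res$pseudo_p,
       n_permutations = n_perm, scheme = weights$scheme)
}

#' Significant coefficients from an unpenalized refit
#'
#' Refits the L1-selected feature set without penalty (ordinary least
#' squares for log-delays, maximum-likelihood logistic regression for the
#' binary indicators) and reports Wald p-values, returning rows with
#' p < alpha sorted ascending by p. Standard post-selection caveat: the
#' p-values do not account for the selection step.
#'
#' @param x Design matrix restricted to the selected features (aliased
#'   columns are dropped with a warning).
#' @param y Target vector.
#' @param task "classification" or "regression".
#' @param alpha Significance threshold.
#' @return data.frame: predictor, coefficient, p_value (significant rows
#'   only, sorted by p); full table in `attr(, "full")`.
#' @export
significant_coefficients <- function(x, y, task = c("classification", "regression"),
                                     alpha = 0.05) {
  task <- match.arg(task)
  df <- data.frame(x, check.names = FALSE)
  df$.y <- y
  fit <- if (task == "regression") {
    stats::lm(.y ~ ., data = df)
  } else {
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  }
  co <- summary(fit)$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    warning("dropped aliased column(s): ", paste(aliased, collapse = ", "))
  }
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  full <- data.frame(predictor = gsub("`", "", rownames(co)),
                     coefficient = co[, 1], p_value = co[, 4],
                     row.names = NULL)
  out <- full[full$p_value < alpha, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Permutation feature importance
#'
#' For each feature, the model score is recomputed after shuffling only
#' that column, `n_repeats` times; importance is the mean score
#' degradation (increase for loss metrics like RMSE, decrease for gain
#' metrics like AUC or accuracy), so positive importance = the feature
#' helps. Ranking ties are broken by feature name.
#'
#' @param predict_fun Function(newx matrix) -> predictions, from a fitted
#'   model.
#' @param x Design matrix the model was fitted on.
#' @param y Target vector.
#' @param metric "rmse", "auc" or "accuracy".
#' @param n_repeats Shuffles per feature.
#' @param seed Integer seed.
#' @return data.frame: feature, importance, rank (1 = most important).
#' @export
permutation_importance <- function(predict_fun, x, y,
                                   metric = c("rmse", "auc", "accuracy"),
                                   n_repeats = 5, seed = 1L) {
  metric <- match.arg(metric)
  task <- if (metric == "rmse") "regression" else "classification"
  if (task == "classification" && !all(y %in% c(0, 1))) {
    stop("metric '", metric, "' requires a binary target")
  }
  score <- function(xm) {
    p <- predict_fun(xm)
    m <- prediction_metrics(p, y, task)
    m[[metric]]
  }
  base <- score(x)
  loss <- metric == "rmse"
  feats <- colnames(x)
  imp <- numeric(length(feats))
  with_local_seed(seed, {
    for (fi in seq_along(feats)) {
      deltas <- vapply(seq_len(n_repeats), function(r) {
        xs <- x
        xs[, fi] <- xs[sample.int(nrow(x)), fi]
        s <- score(xs)
        if (loss) s - base else base - s
      }, numeric(1))
      imp[fi] <- mean(deltas)
    }
  })
  ord <- order(-imp, feats)
  out <- data.frame(feature = feats, importance = imp)
  out$rank <- match(seq_along(feats), ord)
  out[order(out$rank), ]
}
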