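# Staged predictive framework: feature-group assembly for the NS1/NS2/S1/
# S2/S3 specifications, L1 feature selection, four learner families and
# 10-fold cross-validation with pooled out-of-sample metrics.
#
# Feature groups: V survivor characteristics, Z temporal flags, X areal
# socio-economic covariates, Q district dummies, C point coordinates.

.SPEC_GROUPS <- list(NS1 = c("V"),
                     NS2 = c("Z", "V"),
                     S1 = c("X", "Z", "V"),
                     S2 = c("Q", "Z", "V"),
                     S3 = c("X", "C", "Z", "V"))

#' Model specification
#'
#' @param name One of NS1 (survivor only), NS2 (+temporal), S1 (+areal
#'   covariates), S2 (+district dummies), S3 (areal + coordinates).
#' @param target "d_day", "d_week", "d_month" (classification) or
#'   "log_delay" (regression).
#' @param learner "lasso_lm", "random_forest", "gradient_boosting" or
#'   "gaussian_process" (S3 only: needs coordinates).
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed controlling folds, selection and learners.
#' @return list of class "model_spec".
#' @export
model_spec <- function(name = c("NS1", "NS2", "S1", "S2", "S3"),
                       target = c("d_day", "d_week", "d_month", "log_delay"),
                       learner = c("lasso_lm", "random_forest",
                                   "gradient_boosting", "gaussian_process"),
                       cv_folds = 10, seed = 1L) {
  name <- match.arg(name); target <- match.arg(target); learner <- match.arg(learner)
  groups <- .SPEC_GROUPS[[name]]
  if (learner == "gaussian_process" && !("C" %in% groups)) {
    stop("gaussian_process requires point coordinates (specification S3)")
  }
  structure(list(name = name, feature_groups = groups, target = target,
                 learner = learner, cv_folds = as.integer(cv_folds),
                 task = if (target == "log_delay") "regression" else "classification",
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Assemble the design matrix for a model specification
#'
#' Categorical survivor fields are one-hot encoded with a dropped reference
#' level (race "other", age band "25.44"); one season ("fall") is the
#' temporal reference; district dummies drop the first district. Areal
#' covariates come from [event_context()] (tract attributes under the point
#' regime, district aggregates under the centroid regime). Continuous
#' columns are flagged so that standardization can be done with
#' training-fold statistics only inside [fit_predict_cv()].
#'
#' @param events Event table (from [generate_events()] or
#'   [read_events_csv()]), with temporal flags present.
#' @param spec A [model_spec()].
#' @param tracts Tract table (required when group X under point regime).
#' @param district_attrs District attribute table (X under centroid regime).
#' @param regime Coordinate regime for X assignment.
#' @return list: `x` numeric matrix, `y` target vector, `continuous`
#'   logical vector over columns, `coord_cols` names of coordinate columns.
#' @export
assemble_features <- function(events, spec, tracts = NULL, district_attrs = NULL,
                              regime = c("point", "district_centroid")) {
  regime <- match.arg(regime)
  groups <- spec$feature_groups
  blocks <- list(); continuous <- character(0)
  if ("V" %in% groups) {
    v <- survivor_dummies(events)
    v$vict.other <- NULL; v$vict.25.44 <- NULL  # reference levels
    blocks$V <- v
  }
  if ("Z" %in% groups) {
    zc <- c("winter", "spring", "summer", "weekend", "federal", "christian",
            "muslim", "jewish", "hindu", "celebration")
    miss <- setdiff(zc, names(events))
    if (length(miss)) stop("events lack temporal flags: ", paste(miss, collapse = ", "))
    blocks$Z <- events[zc]
  }
  if ("X" %in% groups) {
    if (regime == "point" && is.null(tracts)) stop("group X under point regime needs tracts")
    xa <- event_context(events, tracts, district_attrs, regime)
    blocks$X <- xa
    continuous <- c(continuous, names(xa))
  }
  if ("Q" %in% groups) {
    lev <- sort(unique(events$district_id))
    q <- as.data.frame(lapply(lev[-1], function(l) as.integer(events$district_id == l)))
    names(q) <- paste0("district.", lev[-1])
    blocks$Q <- q
  }
  if ("C" %in% groups) {
    if (is.null(events$lon) || anyNA(events$lon)) stop("group C needs event coordinates")
    blocks$C <- events[c("lon", "lat")]
    continuous <- c(continuous, "lon", "lat")
  }
  x <- as.matrix(do.call(cbind, unname(blocks)))
  if (any(!is.finite(x))) stop("non-finite values in the design matrix")
  y <- events[[spec$target]]
  list(x = x, y = y, continuous = colnames(x) %in% continuous,
       coord_cols = if ("C" %in% groups) c("lon", "lat") else character(0))
}

#' L1 (lasso) feature selection
#'
#' Fits a lasso path with the penalty chosen by inner cross-validation and
#' returns the features with nonzero coefficients at lambda.min;
#' `always_keep` columns (e.g. coordinates in S3) are excluded from the
#' penalised search and always returned.
#'
#' @param x Numeric design matrix (>= 2 candidate features).
#' @param y Target vector.
#' @param task "classification" or "regression".
#' @param always_keep Column names exempt from selection.
#' @param seed Integer seed (inner fold assignment).
#' @param nfolds Inner CV folds.
#' @return Character vector of selected feature names.
#' @export
l1_select <- function(x, y, task = c("classification", "regression"),
                      always_keep = character(0), seed = 1L, nfolds = 5) {
  task <- match.arg(task)
  cand <- setdiff(colnames(x), always_keep)
  if (length(cand) < 2) return(unique(c(cand, always_keep)))
  fam <- if (task == "classification") "binomial" else "gaussian"
  xs <- x[, cand, drop = FALSE]
  with_local_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(xs)))
    fit <- glmnet::cv.glmnet(xs, y, family = fam, foldid = foldid)
    co <- as.matrix(stats::coef(fit, s = "lambda.min"))[-1, 1]
    sel <- names(co)[co != 0]
    if (length(sel) == 0 && length(always_keep) == 0) {
      warning("all lasso coefficients zero: falling back to intercept-only")
    }
    unique(c(sel, always_keep))
  })
}

.make_folds <- function(y, k, task, seed) {
  n <- length(y)
  draw <- function(s) {
    with_local_seed(s, {
      if (task == "classification") {
        f <- integer(n)
        for (cl in unique(y)) {
          idx <- which(y == cl)
          f[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        f
      } else {
        sample(rep_len(seq_len(k), n))
      }
    })
  }
  folds <- draw(seed)
  if (task == "classification") {
    bad <- any(vapply(seq_len(k), function(i) length(unique(y[folds != i])) < 2, logical(1)))
    if (bad) folds <- draw(derive_seed(seed, 99L))
    bad <- any(vapply(seq_len(k), function(i) length(unique(y[folds != i])) < 2, logical(1)))
    if (bad) stop("a training fold contains a single class")
  }
  folds
}

.fit_learner <- function(learner, x, y, task, seed) {
  if (learner == "lasso_lm") {
    fam <- if (task == "classification") "binomial" else "gaussian"
    fit <- with_local_seed(seed, {
      foldid <- sample(rep_len(seq_len(5), nrow(x)))
      glmnet::cv.glmnet(x, y, family = fam, foldid = foldid)
    })
    function(newx) {
      as.numeric(stats::predict(fit, newx = newx, s = "lambda.min", type = "response"))
    }
  } else if (learner == "random_forest") {
    df <- data.frame(x, check.names = FALSE)
    df$.y <- if (task == "classification") factor(y, levels = c(0, 1)) else y
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = 300, seed = seed, num.threads = 1,
                          probability = task == "classification",
                          respect.unordered.factors = TRUE)
    function(newx) {
      p <- stats::predict(fit, data = data.frame(newx, check.names = FALSE),
                          num.threads = 1)$predictions
      if (task == "classification") p[, "1"] else as.numeric(p)
    }
  } else if (learner == "gradient_boosting") {
    obj <- if (task == "classification") "binary:logistic" else "reg:squarederror"
    fit <- xgboost::xgb.train(
      params = list(objective = obj, eta = 0.1, max_depth = 4,
                    subsample = 0.8, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = 150, verbose = 0)
    function(newx) {
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1)))
    }
  } else if (learner == "gaussian_process") {
    # single squared-exponential kernel over the standardized selected
    # features (coordinates included); fixed kernel width => deterministic
    sigma <- 1 / ncol(x)
    if (task == "classification") {
      yy <- factor(y, levels = c(0, 1))
      fit <- kernlab::gausspr(x, yy, type = "classification",
                              kernel = "rbfdot", kpar = list(sigma = sigma))
      function(newx) kernlab::predict(fit, newx, type = "probabilities")[, "1"]
    } else {
      # var is the noise variance on the internally scaled target; 0.5 says
      # half the variance is noise, a sane prior for noisy social data
      fit <- kernlab::gausspr(x, y, type = "regression",
                              kernel = "rbfdot", kpar = list(sigma = sigma),
                              var = 0.5)
      function(newx) as.numeric(kernlab::predict(fit, newx))
    }
  } else stop("unknown learner")
}

#' Majority-vote baseline accuracy
#'
#' @param y Binary 0/1 target.
#' @return Frequency of the majority class.
#' @export
majority_baseline <- function(y) {
  max(mean(y == 1), mean(y == 0))
}

#' Classification / regression metrics
#'
#' Accuracy at the 0.5 threshold; AUC as the Mann-Whitney rank statistic
#' (0.5 credit for ties); RMSE; R^2 = 1 - SSE/SST on the pooled
#' out-of-sample predictions.
#'
#' @param pred Predicted probabilities (classification) or values.
#' @param truth Observed target.
#' @param task "classification" or "regression".
#' @return Named list of metrics (`auc` is NA for single-class truth).
#' @export
prediction_metrics <- function(pred, truth, task = c("classification", "regression")) {
  task <- match.arg(task)
  stopifnot(length(pred) == length(truth))
  if (task == "classification") {
    acc <- mean((pred >= 0.5) == (truth == 1))
    n1 <- sum(truth == 1); n0 <- sum(truth == 0)
    auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
      r <- rank(pred)
      (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    list(accuracy = acc, auc = auc)
  } else {
    sse <- sum((truth - pred)^2)
    list(rmse = sqrt(mean((truth - pred)^2)),
         r2 = 1 - sse / sum((truth - mean(truth))^2))
  }
}

#' Cross-validated fit and out-of-sample prediction
#'
#' Folds are stratified by class for binary targets and random for
#' regression, fixed by the spec seed. Standardization of continuous
#' columns and L1 selection (lasso and Gaussian-process learners; S3
#' coordinates always retained) happen strictly inside each training fold.
#' Every event is predicted exactly once out-of-sample.
#'
#' @param features Output of [assemble_features()].
#' @param spec A [model_spec()].
#' @return list of class "cv_result": `predictions`, `fold`, `residuals`
#'   (observed minus predicted value/probability), `metrics`, `selected`
#'   (per-fold feature lists), `majority` (classification only).
#' @export
fit_predict_cv <- function(features, spec) {
  x <- features$x; y <- features$y
  task <- spec$task
  k <- spec$cv_folds
  if (nrow(x) < 2 * k) stop("too few events for ", k, "-fold cross-validation")
  folds <- .make_folds(y, k, task, spec$seed)
  pred <- numeric(length(y))
  selected <- vector("list", k)
  uses_selection <- spec$learner %in% c("lasso_lm", "gaussian_process")
  for (i in seq_len(k)) {
    tr <- folds != i; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    # training-fold standardization of continuous columns
    cont <- which(features$continuous)
    for (cidx in cont) {
      mu <- mean(xtr[, cidx]); sdv <- stats::sd(xtr[, cidx])
      if (sdv == 0) sdv <- 1
      xtr[, cidx] <- (xtr[, cidx] - mu) / sdv
      xte[, cidx] <- (xte[, cidx] - mu) / sdv
    }
    fseed <- derive_seed(spec$seed, i)
    if (uses_selection && spec$learner == "gaussian_process") {
      sel <- l1_select(xtr, y[tr], task, always_keep = features$coord_cols, seed = fseed)
      if (length(sel) == 0) sel <- colnames(xtr)
      selected[[i]] <- sel
      xtr <- xtr[, sel, drop = FALSE]; xte <- xte[, sel, drop = FALSE]
    } else if (uses_selection) {
      selected[[i]] <- colnames(xtr)  # lasso penalises internally
    } else {
      selected[[i]] <- colnames(xtr)
    }
    predict_fun <- .fit_learner(spec$learner, xtr, y[tr], task, fseed)
    pred[te] <- predict_fun(xte)
  }
  metrics <- prediction_metrics(pred, y, task)
  structure(list(predictions = pred, fold = folds, residuals = y - pred,
                 metrics = metrics, selected = selected,
                 majority = if (task == "classification") majority_baseline(y) else NULL,
                 spec = spec),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %s / %s / %s, %d folds\n", x$spec$name, x$spec$target,
              x$spec$learner, x$spec$cv_folds))
  for (nm in names(x$metrics)) cat(sprintf("  %s = %.4f\n", nm, x$metrics[[nm]]))
  if (!is.null(x$majority)) cat(sprintf("  majority baseline = %.4f\n", x$majority))
  invisible(x)
}
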