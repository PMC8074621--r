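# shared small dataset for the model tests
ds_small <- generate_events(scenario_preset("spatial", seed = 55, n_events = 600))
iw_small <- intersection_weights(ds_small$tracts, ds_small$districts)
da_small <- aggregate_attributes(ds_small$tracts, iw_small)

test_that("specification names map to the documented feature groups", {
  expect_equal(model_spec("NS1", "d_day", "lasso_lm")$feature_groups, "V")
  expect_equal(model_spec("NS2", "d_day", "lasso_lm")$feature_groups, c("Z", "V"))
  expect_equal(model_spec("S3", "d_day", "lasso_lm")$feature_groups,
               c("X", "C", "Z", "V"))
  expect_error(model_spec("NS1", "d_day", "gaussian_process"),
               "requires point coordinates")
})

test_that("assembled design matrices contain exactly the requested blocks", {
  ev <- ds_small$events
  ns1 <- assemble_features(ev, model_spec("NS1", "d_month", "lasso_lm"))
  expect_true(all(startsWith(colnames(ns1$x), "vict.")))
  expect_false("vict.other" %in% colnames(ns1$x))   # reference level dropped
  expect_false("vict.25.44" %in% colnames(ns1$x))

  s2 <- assemble_features(ev, model_spec("S2", "d_month", "lasso_lm"))
  m <- length(unique(ev$district_id))
  expect_equal(sum(startsWith(colnames(s2$x), "district.")), m - 1)

  s3 <- assemble_features(ev, model_spec("S3", "log_delay", "lasso_lm"),
                          tracts = ds_small$tracts, district_attrs = da_small,
                          regime = "point")
  expect_true(all(c("lon", "lat", "poverty", "federal", "vict.u18") %in% colnames(s3$x)))
  expect_equal(s3$coord_cols, c("lon", "lat"))
  expect_equal(s3$y, ev$log_delay)
})

test_that("L1 selection keeps signal, discards most noise, and honours always_keep", {
  set.seed(10)
  kept_signal <- 0; noise_rate <- numeric(10)
  for (s in 1:10) {
    n <- 800; p_noise <- 15
    x <- cbind(signal = rnorm(n), matrix(rnorm(n * p_noise), n,
               dimnames = list(NULL, paste0("noise", 1:p_noise))))
    y <- 2 * x[, "signal"] + rnorm(n)
    sel <- l1_select(x, y, "regression", seed = s)
    kept_signal <- kept_signal + ("signal" %in% sel)
    noise_rate[s] <- mean(paste0("noise", 1:p_noise) %in% sel)
  }
  expect_equal(kept_signal, 10)
  expect_lte(mean(noise_rate), 0.35)  # lambda.min keeps some noise; most dropped
  sel <- l1_select(cbind(lon = rnorm(100), lat = rnorm(100), a = rnorm(100)),
                   rnorm(100), "regression", always_keep = c("lon", "lat"), seed = 1)
  expect_true(all(c("lon", "lat") %in% sel))
})

test_that("metrics match hand-computed values including tie credit", {
  m <- prediction_metrics(c(0.9, 0.1), c(1, 0), "classification")
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  expect_equal(prediction_metrics(c(0.7, 0.7), c(1, 0), "classification")$auc, 0.5)
  r <- prediction_metrics(c(1, 2, 3), c(1, 2, 3), "regression")
  expect_equal(r$rmse, 0)
  expect_equal(r$r2, 1)
  expect_true(is.na(prediction_metrics(c(0.2, 0.8), c(1, 1), "classification")$auc))
})

test_that("majority baseline equals the majority class frequency", {
  expect_equal(majority_baseline(c(1, 1, 1, 0, 0)), 0.6)
  expect_equal(majority_baseline(c(1, 0)), 0.5)
  expect_equal(majority_baseline(rep(1, 7)), 1)
})

test_that("cross-validation is deterministic and predicts every event once", {
  ev <- ds_small$events
  sp <- model_spec("NS2", "d_month", "random_forest", seed = 7)
  ft <- assemble_features(ev, sp)
  a <- fit_predict_cv(ft, sp)
  b <- fit_predict_cv(ft, sp)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$metrics, b$metrics)
  expect_equal(sort(unique(a$fold)), 1:10)
  expect_equal(length(a$predictions), nrow(ft$x))
  expect_true(a$metrics$auc >= 0 && a$metrics$auc <= 1)

  spg <- model_spec("NS2", "d_month", "gradient_boosting", seed = 7)
  g1 <- fit_predict_cv(ft, spg)
  g2 <- fit_predict_cv(ft, spg)
  expect_identical(g1$predictions, g2$predictions)
})

test_that("a perfectly separable target reaches AUC ~1 and noise stays ~0.5", {
  set.seed(21)
  n <- 400
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x[, "a"] > 0)
  sp <- model_spec("NS1", "d_day", "lasso_lm", seed = 2)
  ft <- list(x = x, y = y, continuous = c(TRUE, TRUE), coord_cols = character(0))
  cv <- fit_predict_cv(ft, sp)
  expect_gte(cv$metrics$auc, 0.99)
  # pure noise target
  y2 <- rbinom(n, 1, 0.5)
  cv2 <- fit_predict_cv(list(x = x, y = y2, continuous = c(TRUE, TRUE),
                             coord_cols = character(0)), sp)
  expect_lt(abs(cv2$metrics$auc - 0.5), 0.12)
})

test_that("regression on pure noise has near-zero out-of-sample R^2", {
  set.seed(31)
  r2 <- vapply(1:5, function(s) {
    n <- 500
    x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5)))
    y <- rnorm(n)
    sp <- model_spec("NS1", "log_delay", "lasso_lm", seed = s)
    fit_predict_cv(list(x = x, y = y, continuous = rep(TRUE, 5),
                        coord_cols = character(0)), sp)$metrics$r2
  }, numeric(1))
  expect_lte(mean(r2), 0.02)
})

test_that("corrupting a test fold's targets does not change its predictions", {
  set.seed(41)
  n <- 300
  x <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- x[, 1] + rnorm(n)
  sp <- model_spec("NS1", "log_delay", "lasso_lm", seed = 9)
  ft <- list(x = x, y = y, continuous = rep(TRUE, 4), coord_cols = character(0))
  cv <- fit_predict_cv(ft, sp)
  fold1 <- cv$fold == 1
  y2 <- y; y2[fold1] <- y2[fold1] + 100  # corrupt only the held-out rows
  cv2 <- fit_predict_cv(list(x = x, y = y2, continuous = rep(TRUE, 4),
                             coord_cols = character(0)), sp)
  expect_equal(cv$predictions[fold1], cv2$predictions[fold1], tolerance = 1e-10)
})

test_that("the Gaussian-process learner runs on S3 features", {
  ds <- generate_events(scenario_preset("spatial", seed = 61, n_events = 250))
  iw <- intersection_weights(ds$tracts, ds$districts)
  da <- aggregate_attributes(ds$tracts, iw)
  sp <- model_spec("S3", "log_delay", "gaussian_process", seed = 3, cv_folds = 5)
  ft <- assemble_features(ds$events, sp, tracts = ds$tracts, district_attrs = da,
                          regime = "point")
  cv <- fit_predict_cv(ft, sp)
  expect_true(is.finite(cv$metrics$rmse))
  expect_true(all(c("lon", "lat") %in% cv$selected[[1]]))
})
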