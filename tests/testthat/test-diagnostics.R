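test_that("rsa_test is calibrated on location-shuffled residuals", {
  set.seed(12)
  ds <- generate_events(scenario_preset("spatial", seed = 70, n_events = 500))
  w <- suppressWarnings(same_district_weights(ds$events$district_id))
  p <- vapply(1:40, function(i) {
    res <- sample(rnorm(500))  # residuals with no spatial structure
    rsa_test(res, w, n_perm = 199, seed = i)$pseudo_p
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.15)
  expect_gte(mean(p < 0.5), 0.25)  # roughly uniform, not degenerate
})

test_that("rsa_test flags spatially structured residuals", {
  ds <- generate_events(scenario_preset("spatial", seed = 71, n_events = 800))
  u <- ds$truth$district_effects
  res <- u[ds$events$district_id] + rnorm(800, 0, 0.3)
  w <- suppressWarnings(same_district_weights(ds$events$district_id))
  expect_lt(rsa_test(res, w, n_perm = 199, seed = 4)$pseudo_p, 0.05)
})

test_that("significant_coefficients recovers an injected effect with its sign", {
  set.seed(5)
  hits <- vapply(1:5, function(s) {
    ds <- generate_events(scenario_preset("spatial", seed = 400 + s,
                                          n_events = 1500))
    ev <- ds$events
    sp <- model_spec("NS2", "log_delay", "lasso_lm", seed = s)
    ft <- assemble_features(ev, sp)
    sel <- l1_select(ft$x, ft$y, "regression", seed = s)
    tab <- significant_coefficients(ft$x[, sel, drop = FALSE], ft$y, "regression")
    ok_fed <- "federal" %in% tab$predictor &&
      tab$coefficient[tab$predictor == "federal"] > 0
    ok_u18 <- "vict.u18" %in% tab$predictor &&
      tab$coefficient[tab$predictor == "vict.u18"] > 0
    ok_fed && ok_u18
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("coefficient flagging has ~alpha type-I rate on pure noise", {
  set.seed(9)
  rates <- vapply(1:30, function(i) {
    n <- 200; p <- 12
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    y <- rnorm(n)
    nrow(significant_coefficients(x, y, "regression")) / p
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.04)
})

test_that("logistic refit works for binary targets", {
  set.seed(14)
  n <- 600
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * x[, "a"]))
  tab <- significant_coefficients(x, y, "classification")
  expect_true("a" %in% tab$predictor)
  expect_gt(tab$coefficient[tab$predictor == "a"], 0)
})

test_that("permutation importance ranks the generating feature first", {
  set.seed(17)
  n <- 500
  x <- cbind(strong = rnorm(n), weak = rnorm(n), none = rnorm(n))
  y <- 3 * x[, "strong"] + 0.3 * x[, "weak"] + rnorm(n, 0, 0.5)
  fit <- ranger::ranger(y = y, x = data.frame(x), num.trees = 200, seed = 1,
                        num.threads = 1)
  pf <- function(newx) predict(fit, data.frame(newx), num.threads = 1)$predictions
  imp <- permutation_importance(pf, x, y, metric = "rmse", n_repeats = 5, seed = 2)
  expect_equal(imp$feature[imp$rank == 1], "strong")
  expect_lt(abs(imp$importance[imp$feature == "none"]),
            0.25 * imp$importance[imp$feature == "strong"])
  expect_setequal(imp$rank, 1:3)
})

test_that("duplicating an informative feature dilutes its importance", {
  set.seed(19)
  n <- 600
  base <- rnorm(n)
  y <- 2 * base + rnorm(n, 0, 0.5)
  x1 <- cbind(sig = base, noise = rnorm(n))
  x2 <- cbind(sig = base, sig2 = base, noise = rnorm(n))
  fit1 <- ranger::ranger(y = y, x = data.frame(x1), num.trees = 300, seed = 1,
                         num.threads = 1)
  fit2 <- ranger::ranger(y = y, x = data.frame(x2), num.trees = 300, seed = 1,
                         num.threads = 1)
  p1 <- function(newx) predict(fit1, data.frame(newx), num.threads = 1)$predictions
  p2 <- function(newx) predict(fit2, data.frame(newx), num.threads = 1)$predictions
  i1 <- permutation_importance(p1, x1, y, "rmse", n_repeats = 5, seed = 3)
  i2 <- permutation_importance(p2, x2, y, "rmse", n_repeats = 5, seed = 3)
  expect_lt(i2$importance[i2$feature == "sig"], i1$importance[i1$feature == "sig"])
})
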