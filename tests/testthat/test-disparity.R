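test_that("gini matches hand-evaluated double sums and is scale invariant", {
  expect_equal(gini(c(5, 5, 5)), 0)
  expect_equal(gini(c(0, 1)), 0.5)          # |0-1|*2 / (2*4*0.5)
  v <- c(2, 7, 1, 9, 4)
  # direct double-sum evaluation
  direct <- sum(outer(v, v, function(a, b) abs(a - b))) / (2 * length(v)^2 * mean(v))
  expect_equal(gini(v), direct, tolerance = 1e-12)
  expect_equal(gini(v), gini(10 * v), tolerance = 1e-12)
  expect_error(gini(c(-1, 2)), "nonnegative")
  expect_error(gini(c(0, 0)), "all-zero")
})

test_that("inter-decile range follows the linear-interpolation quantile rule", {
  expect_equal(interdecile_range(rep(4, 12)), 0)
  expect_equal(interdecile_range(seq(0, 100, by = 10)), 80)
  v <- rexp(40)
  expect_equal(interdecile_range(2 * v), 2 * interdecile_range(v), tolerance = 1e-12)
  expect_error(interdecile_range(1:9), "at least 10")
})

test_that("permutation preserves district counts and is exchangeable", {
  districts <- c("A", "A", "A", "B", "B")
  set.seed(4)
  for (i in 1:20) {
    perm <- permute_assignments(districts)
    expect_equal(sort(table(perm)), sort(table(districts)), ignore_attr = TRUE)
  }
  # delay #1 should land in district A with frequency 3/5
  hits <- mean(vapply(1:4000, function(i) permute_assignments(districts)[1] == "A",
                      logical(1)))
  expect_equal(hits, 3 / 5, tolerance = 0.03)
  expect_warning(permute_assignments(c("A", "A")), "single district")
})

test_that("ranked-median envelope flags nothing when all delays are equal", {
  ev <- toy_events(rep(5, 60), districts = rep(c("A", "B", "C"), each = 20))
  env <- ranked_median_envelope(ev, n_perm = 200, seed = 1)
  expect_true(all(env$table$observed == 5))
  expect_false(any(env$table$outside))
  expect_true(all(diff(env$table$null_mean) >= 0))  # monotone in rank
  expect_true(all(env$table$lower <= env$table$null_mean &
                  env$table$null_mean <= env$table$upper))
  expect_warning(ranked_median_envelope(ev, n_perm = 50, seed = 1), "unstable")
})

test_that("envelope flags extreme ranks under strong district effects", {
  ds <- generate_events(scenario_preset("spatial", seed = 8))
  env <- ranked_median_envelope(ds$events, n_perm = 300, seed = 2)
  m <- nrow(env$table)
  expect_true(any(env$table$outside[c(1:3, (m - 2):m)]))
})

test_that("disparity p-values follow the add-one one-sided convention", {
  set.seed(6)
  # observed much larger than any permutation: p = 1/(B+1)
  ev <- toy_events(c(rep(1, 50), rep(400, 10)),  # one extreme district
                   districts = rep(c("A", "B", "C", "D", "E", "F"), each = 10))
  d <- disparity_test(ev, "gini", n_perm = 199, seed = 3)
  # permutations can tie the observed maximal gini (same median multiset),
  # so p is 1/200 plus the tie count, never below the add-one floor
  expect_gte(d$p_value, 1 / 200)
  expect_lte(d$p_value, 3 / 200)
  # constant delays: every permuted gini equals the observed 0 => p = 1
  ev2 <- toy_events(rep(3, 40), districts = rep(c("A", "B", "C", "D"), each = 10))
  d2 <- disparity_test(ev2, "gini", n_perm = 99, seed = 3)
  expect_equal(d2$p_value, 1)
})

test_that("disparity tests have power under the spatial preset", {
  p <- vapply(1:5, function(s) {
    ev <- generate_events(scenario_preset("spatial", seed = 300 + s))$events
    disparity_test(ev, "gini", n_perm = 199, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.8)
})
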