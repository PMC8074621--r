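test_that("scenario validation rejects impossible configurations", {
  expect_error(scenario_config(grid_tracts = c(4, 4), district_factor = 3),
               "divide")
  expect_error(scenario_config(n_events = 0), "n_events")
  expect_error(scenario_config(heaping_prob = 1.2), "heaping_prob")
  expect_error(scenario_config(covariate_effects = c(1, 2)), "named")
})

test_that("areas tile the rectangle and districts are whole-tract blocks", {
  cfg <- scenario_config(grid_tracts = c(4, 4), district_factor = 2, seed = 3)
  ar <- generate_areas(cfg)
  expect_equal(nrow(ar$tracts), 16L)
  expect_equal(nrow(ar$districts), 4L)
  expect_equal(sum(vapply(ar$tracts$geometry, poly_area, numeric(1))), 16)
  expect_equal(sum(vapply(ar$districts$geometry, poly_area, numeric(1))), 16)
  # each district covers exactly 4 tracts
  expect_equal(unname(table(ar$tracts$district_id)), rep(4L, 4L),
               ignore_attr = TRUE)
  expect_true(all(ar$tracts$pop.total > 0))
})

test_that("same seed produces bit-identical datasets", {
  a <- generate_events(scenario_preset("spatial", seed = 42))
  b <- generate_events(scenario_preset("spatial", seed = 42))
  expect_identical(a$events, b$events)
  expect_identical(a$tracts, b$tracts)
  expect_false(identical(a$events$delay_days,
                         generate_events(scenario_preset("spatial", seed = 43))$events$delay_days))
})

test_that("every event lies inside exactly one district and carries a tract id", {
  ds <- generate_events(scenario_preset("spatial", seed = 5, n_events = 400))
  ev <- ds$events
  expect_true(all(ev$district_id %in% ds$districts$id))
  expect_true(all(ev$tract_id %in% ds$tracts$id))
  # point-in-polygon agreement with the recorded district
  for (i in sample(nrow(ev), 25)) {
    g <- ds$districts$geometry[[match(ev$district_id[i], ds$districts$id)]]
    expect_true(point_in_polygon(ev$lon[i], ev$lat[i], g))
  }
})

test_that("the centroid regime collapses coordinates onto district centroids", {
  ds <- generate_events(scenario_preset("ny_style", seed = 5, n_events = 300))
  ev <- ds$events
  idx <- match(ev$district_id, ds$districts$id)
  expect_equal(ev$lon, ds$districts$cx[idx])
  expect_equal(ev$lat, ds$districts$cy[idx])
  expect_true(all(is.na(ev$tract_id)))
})

test_that("forced heaping puts every occurrence on the 1st or 15th", {
  ds <- generate_events(scenario_preset("null", seed = 9, heaping_prob = 1,
                                        n_events = 500))
  dom <- as.POSIXlt(ds$events$occurrence_date)$mday
  expect_true(all(dom %in% c(1L, 15L)))
})

test_that("an injected holiday effect shifts mean log-delay by its magnitude", {
  # Monte-Carlo check against the generative mean: a +1 federal effect on the
  # log(1+delay) scale separates federal/non-federal group means by ~1
  ds <- generate_events(scenario_config(n_events = 5000, seed = 77,
                                        covariate_effects = c(federal = 1.0),
                                        tail_mixture = c(0, 3)))
  ev <- ds$events
  gap <- mean(ev$log_delay[ev$federal == 1]) - mean(ev$log_delay[ev$federal == 0])
  expect_gt(sum(ev$federal), 50)
  expect_equal(gap, 1.0, tolerance = 0.2)
})

test_that("the default preset has the documented heavy right tail", {
  ev <- generate_events(scenario_preset("null", seed = 21, n_events = 4000))$events
  expect_gt(quantile(ev$delay_days, 0.99), 10 * median(ev$delay_days))
})

test_that("null scenario district medians show no spatial structure", {
  # single-seed sanity check; full calibration lives in the acceptance suite
  ds <- generate_events(scenario_preset("null", seed = 31))
  s <- area_summaries(ds$events, ds$districts)
  occ <- s[s$defined, ]
  qw <- queen_weights(ds$districts$geometry[match(occ$id, ds$districts$id)],
                      ids = occ$id)
  gm <- global_moran(occ$median_delay, qw, n_perm = 499, seed = 1)
  expect_gt(gm$pseudo_p, 0.01)
})

test_that("spatial preset induces significant Moran's I on district delays", {
  hits <- vapply(1:5, function(s) {
    ds <- generate_events(scenario_preset("spatial", seed = 100 + s))
    su <- area_summaries(ds$events, ds$districts)
    occ <- su[su$defined, ]
    qw <- queen_weights(ds$districts$geometry[match(occ$id, ds$districts$id)],
                        ids = occ$id)
    gm <- global_moran(tapply(ds$events$log_delay,
                              factor(ds$events$district_id, levels = occ$id),
                              mean),
                       qw, n_perm = 499, seed = s)
    gm$pseudo_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
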