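make_tracts <- function(polys, pop, extra = NULL) {
  df <- data.frame(id = sprintf("T%02d", seq_along(polys)), pop.total = pop)
  if (!is.null(extra)) df <- cbind(df, extra)
  df$geometry <- I(polys)
  df
}
make_districts <- function(polys) {
  data.frame(id = sprintf("D%02d", seq_along(polys)),
             geometry = I(polys))
}

test_that("containment, split and population-ratio weights are exact", {
  tracts <- make_tracts(list(rect_poly(0, 0, 1, 1), rect_poly(1, 0, 2, 1)),
                        pop = c(100, 300))
  districts <- make_districts(list(rect_poly(0, 0, 2, 1)))
  w <- intersection_weights(tracts, districts)
  expect_equal(w$area_fraction, c(1, 1))
  expect_equal(w$population_proportion, c(0.25, 0.75))

  # unit square split exactly in half
  tr2 <- make_tracts(list(rect_poly(0, 0, 1, 1)), pop = 10)
  di2 <- make_districts(list(rect_poly(0, 0, 0.5, 1), rect_poly(0.5, 0, 1, 1)))
  w2 <- intersection_weights(tr2, di2)
  expect_equal(w2$area_fraction, c(0.5, 0.5))
})

test_that("weights sum to one per tract and per district under exact tiling", {
  ar <- generate_areas(scenario_config(grid_tracts = c(6, 6), district_factor = 3,
                                       seed = 11))
  w <- intersection_weights(ar$tracts, ar$districts)
  expect_lt(max(abs(tapply(w$area_fraction, w$tract_id, sum) - 1)), 1e-9)
  expect_lt(max(abs(tapply(w$population_proportion, w$district_id, sum) - 1)), 1e-9)
  expect_true(all(w$area_fraction >= 0 & w$area_fraction <= 1 + 1e-12))
})

test_that("aggregation conserves totals and fixes constants", {
  ar <- generate_areas(scenario_config(grid_tracts = c(6, 6), district_factor = 2,
                                       seed = 13))
  tr <- ar$tracts
  tr$const <- 3.14
  cls <- rbind(attribute_classes(), data.frame(name = "const", class = "intensive"))
  w <- intersection_weights(tr, ar$districts)
  agg <- aggregate_attributes(tr, w, classes = cls)
  expect_equal(sum(agg$pop.total), sum(tr$pop.total))
  expect_equal(sum(agg$occ.units), sum(tr$occ.units))
  expect_equal(agg$const, rep(3.14, nrow(agg)))
  # equal-population tracts with poverty 10 / 30 average to 20
  t2 <- make_tracts(list(rect_poly(0, 0, 1, 1), rect_poly(1, 0, 2, 1)),
                    pop = c(50, 50), extra = data.frame(poverty = c(10, 30)))
  w2 <- intersection_weights(t2, make_districts(list(rect_poly(0, 0, 2, 1))))
  a2 <- aggregate_attributes(t2, w2, attributes = "poverty")
  expect_equal(a2$poverty, 20)
})

test_that("aggregation is the identity when districts equal tracts", {
  ar <- generate_areas(scenario_config(grid_tracts = c(4, 4), district_factor = 1,
                                       seed = 17))
  w <- intersection_weights(ar$tracts, ar$tracts)
  agg <- aggregate_attributes(ar$tracts, w)
  for (a in setdiff(names(agg), "id")) {
    expect_equal(agg[[a]][match(ar$tracts$id, agg$id)], ar$tracts[[a]],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("event context returns tract attributes (point) or district aggregates", {
  ar <- generate_areas(scenario_config(grid_tracts = c(4, 4), district_factor = 2,
                                       seed = 19))
  ev <- data.frame(id = 1:2, lon = c(0.5, 3.5), lat = c(0.5, 3.5),
                   district_id = c("D001", "D004"))
  got <- event_context(ev, ar$tracts, regime = "point", attributes = "poverty")
  k1 <- which(ar$tracts$row == 1 & ar$tracts$col == 1)
  k2 <- which(ar$tracts$row == 4 & ar$tracts$col == 4)
  expect_equal(got$poverty, ar$tracts$poverty[c(k1, k2)])

  w <- intersection_weights(ar$tracts, ar$districts)
  agg <- aggregate_attributes(ar$tracts, w)
  got2 <- event_context(ev, ar$tracts, district_attrs = agg,
                        regime = "district_centroid", attributes = "poverty")
  expect_equal(got2$poverty, agg$poverty[match(ev$district_id, agg$id)])

  expect_error(event_context(data.frame(id = 1, lon = 99, lat = 99),
                             ar$tracts, regime = "point"),
               "outside all tracts")
})

test_that("boundary points are assigned to the smallest tract id", {
  # the point (1, 0.5) lies on the shared edge of tracts T01 and T02
  tracts <- make_tracts(list(rect_poly(0, 0, 1, 1), rect_poly(1, 0, 2, 1)),
                        pop = c(1, 1), extra = data.frame(poverty = c(5, 9)))
  expect_true(point_in_polygon(1, 0.5, tracts$geometry[[1]]))
  expect_true(point_in_polygon(1, 0.5, tracts$geometry[[2]]))
  got <- event_context(data.frame(id = 1, lon = 1, lat = 0.5), tracts,
                       regime = "point", attributes = "poverty")
  expect_equal(got$poverty, 5)
})
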