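# Population-weighted areal aggregation: tract attributes onto districts
# via polygon-interior intersection, assuming a uniformly distributed
# population within each tract.

#' Tract-district intersection weights
#'
#' For every intersecting (tract k, district j) pair computes the area
#' fraction `P^A_{j|k} = area(interior(b_k) intersect interior(a_j)) / area(b_k)`,
#' the apportioned population `x_{k&j} = P^A_{j|k} * x_k`, and the
#' within-district population proportion `P^x_{k|j} = x_{k&j} / x_j` with
#' `x_j = sum_k x_{k&j}`. Pairs with area fraction below `sliver_tol` are
#' dropped. Districts with zero population are flagged and excluded from
#' the population proportions.
#'
#' @param tracts data.frame with columns id, pop.total (or `population`)
#'   and a `geometry` list column.
#' @param districts data.frame with columns id and `geometry`.
#' @param sliver_tol Minimum retained area fraction.
#' @return data.frame: tract_id, district_id, area_fraction,
#'   population_share, population_proportion.
#' @export
intersection_weights <- function(tracts, districts, sliver_tol = 1e-9) {
  pop <- if ("pop.total" %in% names(tracts)) tracts$pop.total else tracts$population
  if (is.null(pop)) stop("tracts need a pop.total (or population) column")
  if (any(pop < 0)) stop("tract populations must be nonnegative")
  for (i in seq_len(nrow(tracts))) validate_polygon(tracts$geometry[[i]], tracts$id[i])
  for (i in seq_len(nrow(districts))) validate_polygon(districts$geometry[[i]], districts$id[i])
  res <- list()
  for (k in seq_len(nrow(tracts))) {
    bk <- tracts$geometry[[k]]
    ak_area <- poly_area(bk)
    for (j in seq_len(nrow(districts))) {
      a <- poly_intersection_area(bk, districts$geometry[[j]])
      frac <- a / ak_area
      if (frac >= sliver_tol) {
        res[[length(res) + 1]] <- data.frame(
          tract_id = tracts$id[k], district_id = districts$id[j],
          area_fraction = frac, population_share = frac * pop[k])
      }
    }
  }
  w <- do.call(rbind, res)
  xj <- tapply(w$population_share, w$district_id, sum)
  empty <- names(xj)[xj == 0]
  if (length(empty)) {
    warning("district(s) with zero population excluded from population weighting: ",
            paste(empty, collapse = ", "))
  }
  denom <- as.numeric(xj[w$district_id])
  w$population_proportion <- ifelse(denom > 0, w$population_share / denom, NA_real_)
  rownames(w) <- NULL
  w
}

#' Aggregate tract attributes onto districts
#'
#' Intensive attributes (percentages, medians, averages) are aggregated as
#' population-proportion-weighted means `sum_k P^x_{k|j} attr_k`; extensive
#' attributes (totals) are area-apportioned and summed,
#' `sum_k P^A_{j|k} attr_k`, which conserves citywide totals.
#'
#' @param tracts Tract table with attribute columns.
#' @param weights Output of [intersection_weights()].
#' @param classes data.frame(name, class) mapping each attribute to
#'   "intensive" or "extensive"; defaults to [attribute_classes()].
#' @param attributes Attribute names to aggregate (default: all classified
#'   columns present in `tracts`).
#' @return data.frame with one row per district and aggregated columns.
#' @export
aggregate_attributes <- function(tracts, weights, classes = attribute_classes(),
                                 attributes = NULL) {
  if (is.null(attributes)) attributes <- intersect(classes$name, names(tracts))
  missing_cls <- setdiff(attributes, classes$name)
  if (length(missing_cls)) {
    stop("no intensive/extensive classification for: ", paste(missing_cls, collapse = ", "))
  }
  kidx <- match(weights$tract_id, tracts$id)
  districts <- sort(unique(weights$district_id))
  out <- data.frame(id = districts)
  grp <- factor(weights$district_id, levels = districts)
  for (a in attributes) {
    vals <- tracts[[a]][kidx]
    if (anyNA(vals)) stop("missing attribute '", a, "' for a contributing tract")
    cls <- classes$class[classes$name == a]
    wcol <- if (cls == "extensive") weights$area_fraction else weights$population_proportion
    out[[a]] <- as.numeric(tapply(wcol * vals, grp, sum))
  }
  out
}

#' Areal context for events
#'
#' Under the "point" regime each event receives the raw attributes of the
#' census tract containing its coordinates (boundary ties go to the
#' lexicographically smallest tract id); under the "district_centroid"
#' regime each event receives its district's aggregated attributes.
#'
#' @param events Event table (needs lon/lat for "point", district_id for
#'   "district_centroid").
#' @param tracts Tract table with geometry and attributes.
#' @param district_attrs District attribute table from
#'   [aggregate_attributes()] (centroid regime only).
#' @param regime "point" or "district_centroid".
#' @param attributes Attribute columns to return.
#' @return data.frame of areal covariates, one row per event.
#' @export
event_context <- function(events, tracts, district_attrs = NULL,
                          regime = c("point", "district_centroid"),
                          attributes = NULL) {
  regime <- match.arg(regime)
  if (regime == "district_centroid") {
    if (is.null(district_attrs)) stop("district_attrs required under the centroid regime")
    if (is.null(attributes)) attributes <- setdiff(names(district_attrs), "id")
    idx <- match(events$district_id, district_attrs$id)
    if (anyNA(idx)) stop("events reference districts missing from district_attrs")
    return(district_attrs[idx, attributes, drop = FALSE])
  }
  if (is.null(attributes)) attributes <- intersect(attribute_classes()$name, names(tracts))
  bb <- t(vapply(tracts$geometry, function(p) {
    c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  }, numeric(4)))
  ord <- order(tracts$id)
  n <- nrow(events)
  idx <- integer(n)
  for (i in seq_len(n)) {
    px <- events$lon[i]; py <- events$lat[i]
    cand <- which(bb[, 1] <= px & bb[, 2] >= px & bb[, 3] <= py & bb[, 4] >= py)
    hit <- cand[vapply(cand, function(k) {
      point_in_polygon(px, py, tracts$geometry[[k]])
    }, logical(1))]
    if (length(hit) == 0) {
      stop(sprintf("event %s at (%.6f, %.6f) falls outside all tracts",
                   events$id[i], px, py))
    }
    # boundary tie: lexicographically smallest tract id wins
    idx[i] <- hit[order(tracts$id[hit])][1]
  }
  tracts[idx, attributes, drop = FALSE]
}
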