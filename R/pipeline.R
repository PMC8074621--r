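# File I/O (events CSV, areas GeoJSON) and the end-to-end pipeline driver.

#' Write / read event tables as CSV
#'
#' ISO-8601 dates, stable column names. Reading recomputes the derived
#' delay columns and drops rows whose report date precedes the occurrence
#' date (logged count), plus rows with missing mandatory fields.
#'
#' @param events Event data.frame.
#' @param path File path.
#' @return `read_events_csv`: the validated event table.
#' @export
write_events_csv <- function(events, path) {
  drop <- intersect(c("geometry"), names(events))
  utils::write.csv(events[setdiff(names(events), drop)], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("id", "occurrence_date", "report_date", "district_id")
  miss <- setdiff(mandatory, names(ev))
  if (length(miss)) stop("events CSV lacks mandatory column(s): ", paste(miss, collapse = ", "))
  ev$occurrence_date <- as.Date(ev$occurrence_date)
  ev$report_date <- as.Date(ev$report_date)
  bad <- is.na(ev$occurrence_date) | is.na(ev$report_date)
  if (any(bad)) {
    message("read_events_csv: dropped ", sum(bad), " row(s) with unparseable dates (lines ",
            paste(utils::head(which(bad) + 1, 5), collapse = ", "), " ...)")
    ev <- ev[!bad, , drop = FALSE]
  }
  ev$delay_days <- compute_delay(ev$occurrence_date, ev$report_date)
  neg <- is.na(ev$delay_days)
  if (any(neg)) {
    message("read_events_csv: dropped ", sum(neg), " row(s) with negative delays")
    ev <- ev[!neg, , drop = FALSE]
  }
  ev <- cbind(ev[setdiff(names(ev), c("d_day", "d_week", "d_month", "log_delay"))],
              binarize_delay(ev$delay_days))
  ev$log_delay <- log_delay(ev$delay_days)
  ev
}

#' Write / read area tables as GeoJSON
#'
#' Areas are a data.frame with an `id` column, attribute columns and a
#' `geometry` list column of vertex matrices; stored as a FeatureCollection
#' of Polygons with the attributes as properties.
#'
#' @param areas Area data.frame with `geometry` list column.
#' @param path File path.
#' @return `read_areas`: the area data.frame.
#' @export
write_areas_geojson <- function(areas, path) {
  attr_cols <- setdiff(names(areas), "geometry")
  features <- lapply(seq_len(nrow(areas)), function(i) {
    ring <- areas$geometry[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close the ring
    list(type = "Feature",
         properties = as.list(areas[i, attr_cols, drop = FALSE]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) as.numeric(ring[r, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_areas_geojson
#' @export
read_areas <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    props <- f$properties
    id <- if (!is.null(props$id)) props$id else "<unnamed>"
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon")) {
      stop("feature '", id, "' is not a Polygon")
    }
    ring <- f$geometry$coordinates[[1]]
    mat <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    if (nrow(mat) >= 2 && all(mat[1, ] == mat[nrow(mat), ])) mat <- mat[-nrow(mat), , drop = FALSE]
    if (nrow(mat) < 3 || any(!is.finite(mat))) stop("invalid polygon in feature '", id, "'")
    validate_polygon(mat, id)
    c(props, list(geometry = list(mat)))
  })
  props <- lapply(rows, function(r) as.data.frame(r[setdiff(names(r), "geometry")],
                                                  stringsAsFactors = FALSE))
  out <- do.call(rbind, props)
  out$geometry <- I(lapply(rows, function(r) r$geometry[[1]]))
  out
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Generates a scenario, computes district delay summaries, global Moran's
#' I on district median delays, the ranked-median disparity envelope with
#' Gini and inter-decile-range permutation tests, population-weighted
#' district covariates, the staged model grid under cross-validation, and
#' residual spatial-autocorrelation diagnostics; writes every table as CSV
#' plus a machine-readable JSON manifest into `out_dir`.
#'
#' @param preset Scenario preset name (see [scenario_preset()]).
#' @param seed Integer seed for all stages.
#' @param out_dir Output directory (created if needed).
#' @param specs Model specification names to run.
#' @param targets Target variables to run.
#' @param learner Learner for the model grid.
#' @param n_perm Permutations for Moran/disparity/RSA tests.
#' @param rsa_k k for the kNN residual weights (point regimes).
#' @param ... Overrides forwarded to [scenario_preset()].
#' @return Invisibly, a list with every computed artefact.
#' @export
run_pipeline <- function(preset = "spatial", seed = 1L, out_dir = tempdir(),
                         specs = c("NS1", "NS2", "S1", "S2", "S3"),
                         targets = c("d_month", "log_delay"),
                         learner = "lasso_lm", n_perm = 199, rsa_k = 50, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scenario_preset(preset, seed = seed, ...)
  ds <- generate_events(cfg)
  ev <- ds$events
  message("pipeline: ", nrow(ev), " events, ", nrow(ds$districts), " districts")

  summ <- area_summaries(ev, ds$districts)
  occupied <- summ[summ$defined, ]
  qw <- queen_weights(ds$districts$geometry[match(occupied$id, ds$districts$id)],
                      ids = occupied$id)
  moran_med <- global_moran(occupied$median_delay, qw, n_perm = n_perm,
                            seed = derive_seed(seed, 11L))
  env <- ranked_median_envelope(ev, n_perm = max(n_perm, 199),
                                seed = derive_seed(seed, 12L))
  disp <- lapply(c("gini", "idr"), function(s) {
    d <- disparity_test(ev, s, n_perm = n_perm, seed = derive_seed(seed, 13L))
    data.frame(statistic = s, observed = d$observed, p_value = d$p_value)
  })
  disp <- do.call(rbind, disp)

  iw <- intersection_weights(ds$tracts, ds$districts)
  dattr <- aggregate_attributes(ds$tracts, iw)

  regime <- cfg$coordinate_regime
  grid <- expand.grid(spec = specs, target = targets, stringsAsFactors = FALSE)
  metrics_rows <- list(); rsa_rows <- list()
  wts <- if (regime == "point") {
    knn_weights(as.matrix(ev[, c("lon", "lat")]), k = min(rsa_k, nrow(ev) - 1))
  } else {
    same_district_weights(ev$district_id)
  }
  for (g in seq_len(nrow(grid))) {
    sp <- model_spec(grid$spec[g], grid$target[g], learner,
                     seed = derive_seed(seed, 20L + g))
    ft <- assemble_features(ev, sp, tracts = ds$tracts, district_attrs = dattr,
                            regime = regime)
    cv <- fit_predict_cv(ft, sp)
    metrics_rows[[g]] <- data.frame(spec = sp$name, target = sp$target,
                                    learner = learner,
                                    as.data.frame(cv$metrics),
                                    majority = if (is.null(cv$majority)) NA else cv$majority)
    rsa <- rsa_test(cv$residuals, wts, n_perm = n_perm,
                    seed = derive_seed(seed, 40L + g))
    rsa_rows[[g]] <- data.frame(spec = sp$name, target = sp$target,
                                moran_i = rsa$statistic, p_value = rsa$pseudo_p,
                                scheme = rsa$scheme)
    message("pipeline: ", sp$name, "/", sp$target, " done")
  }
  metrics <- do.call(rbind, metrics_rows)
  rsa <- do.call(rbind, rsa_rows)

  # S3 coefficient table on log-delays
  sp3 <- model_spec("S3", "log_delay", "lasso_lm", seed = derive_seed(seed, 60L))
  ft3 <- assemble_features(ev, sp3, tracts = ds$tracts, district_attrs = dattr,
                           regime = regime)
  xs <- ft3$x
  xs[, ft3$continuous] <- scale(xs[, ft3$continuous])
  sel <- l1_select(xs, ft3$y, "regression", always_keep = ft3$coord_cols,
                   seed = derive_seed(seed, 61L))
  coefs <- significant_coefficients(xs[, sel, drop = FALSE], ft3$y, "regression")

  write <- function(obj, name) utils::write.csv(obj, file.path(out_dir, name), row.names = FALSE)
  write(summ, "area_summaries.csv")
  write(env$table, "ranked_median_envelope.csv")
  write(disp, "disparity_tests.csv")
  write(metrics, "model_metrics.csv")
  write(rsa, "residual_autocorrelation.csv")
  write(coefs, "significant_coefficients.csv")
  write(weights_edge_list(qw), "district_queen_weights.csv")
  write(iw, "intersection_weights.csv")
  manifest <- list(preset = preset, seed = seed,
                   config = cfg[setdiff(names(cfg), "covariate_effects")],
                   covariate_effects = as.list(cfg$covariate_effects),
                   district_effects = as.list(ds$truth$district_effects),
                   n_events = nrow(ev), n_districts = nrow(ds$districts),
                   moran_median_delay = list(I = moran_med$statistic,
                                             p = moran_med$pseudo_p),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(dataset = ds, summaries = summ, moran = moran_med,
                 envelope = env, disparity = disp, metrics = metrics,
                 rsa = rsa, coefficients = coefs, manifest = manifest))
}
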