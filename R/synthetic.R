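# Synthetic generator: a tract grid with spatially structured socio-economic
# attributes, districts as blocks of tracts, and event records whose
# log(1+delay) carries survivor/temporal covariate effects plus a
# district-level spatial effect.

# queen-smooth a rows x cols matrix: each cell becomes the mean of its
# 3x3 neighbourhood (clipped at the grid edge)
.grid_smooth <- function(m, passes = 1) {
  nr <- nrow(m); nc <- ncol(m)
  for (p in seq_len(passes)) {
    s <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      r_src <- max(1, 1 - dr):min(nr, nr - dr)
      c_src <- max(1, 1 - dc):min(nc, nc - dc)
      s[r_src + dr, c_src + dc] <- s[r_src + dr, c_src + dc] + m[r_src, c_src]
      cnt[r_src + dr, c_src + dc] <- cnt[r_src + dr, c_src + dc] + 1
    }
    m <- s / cnt
  }
  m
}

#' Classification of areal attributes as intensive or extensive
#'
#' Intensive attributes (percentages, medians, averages) are aggregated as
#' population-weighted means; extensive ones (totals) are area-apportioned
#' and summed. Shipped as a plain-text config table.
#'
#' @return data.frame with columns `name`, `class`.
#' @export
attribute_classes <- function() {
  path <- system.file("extdata", "attribute_classes.csv", package = "reportlag")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Generate the synthetic tract grid and district partition
#'
#' Tracts are unit squares tiling a `rows` x `cols` rectangle; districts are
#' `district_factor`-square blocks of tracts (so they exactly tile the same
#' rectangle). A latent Gaussian field (iid normal, queen-smoothed twice,
#' standardized) drives the spatially structured socio-economic attributes
#' (poverty, income, schooling, insurance, unemployment); the remaining
#' attributes are spatially unstructured. The latent field is recorded per
#' tract for parameter-recovery tests.
#'
#' @param config A [scenario_config()].
#' @return list(tracts, districts): data.frames with an `id` column, a
#'   `geometry` list column of vertex matrices, grid indices and (for
#'   tracts) the attribute columns of [attribute_classes()].
#' @export
generate_areas <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- config$grid_tracts[1]; cols <- config$grid_tracts[2]
  f <- config$district_factor
  with_local_seed(derive_seed(config$seed, 1L), {
    n_tr <- rows * cols
    grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))
    latent_m <- .grid_smooth(matrix(stats::rnorm(n_tr), rows, cols), passes = 2)
    latent <- latent_m[cbind(grid$row, grid$col)]
    latent <- as.numeric(scale(latent))
    tracts <- data.frame(
      id = sprintf("T%04d", seq_len(n_tr)),
      row = grid$row, col = grid$col,
      latent = latent
    )
    nz <- function(sd = 1) stats::rnorm(n_tr, 0, sd)
    lgs <- function(eta) 100 * stats::plogis(eta)
    tracts$pop.total <- round(stats::rlnorm(n_tr, 8.2, 0.3))
    tracts$occ.units <- round(tracts$pop.total / 2.6 * exp(nz(0.1)))
    tracts$pop.male <- lgs(stats::qlogis(0.49) + 0.05 * nz())
    agec <- matrix(stats::rgamma(n_tr * 3, shape = rep(c(25, 55, 12), each = n_tr)), n_tr)
    agec <- 100 * agec / rowSums(agec)
    tracts$pop.u20 <- agec[, 1]; tracts$pop.20.64 <- agec[, 2]; tracts$pop.o64 <- agec[, 3]
    tracts$pop.married <- lgs(0.15 * nz())
    race <- matrix(stats::rgamma(n_tr * 6, shape = rep(c(40, 22, 1, 12, 0.5, 25), each = n_tr)), n_tr)
    race <- 100 * race / rowSums(race)
    tracts$pop.white <- race[, 1]; tracts$pop.black <- race[, 2]
    tracts$pop.native <- race[, 3]; tracts$pop.asian <- race[, 4]
    tracts$pop.pacific <- race[, 5]; tracts$pop.latino <- race[, 6]
    tracts$occupants.1.5 <- lgs(-3 + 0.4 * latent + 0.3 * nz())
    tracts$rent.35.income <- lgs(-0.8 + 0.3 * latent + 0.3 * nz())
    tracts$pop.single.hh <- lgs(-1 + 0.2 * nz())
    tracts$hh.size <- pmax(1, 2.6 + 0.15 * latent + 0.2 * nz())
    tracts$no.school <- lgs(-1.9 + 0.6 * latent + 0.3 * nz())
    tracts$poverty <- lgs(-1.7 + 0.8 * latent + 0.3 * nz())
    tracts$med.income <- exp(10.8 - 0.35 * latent + 0.15 * nz())
    tracts$pop.no.insur <- lgs(-2 + 0.5 * latent + 0.3 * nz())
    tracts$pop.unempl <- lgs(-2.4 + 0.4 * latent + 0.3 * nz())
    lan <- matrix(stats::rgamma(n_tr * 2, shape = rep(c(60, 25), each = n_tr)), n_tr)
    lan <- 100 * lan / (rowSums(lan) + stats::rgamma(n_tr, 15))
    tracts$lan.english <- lan[, 1]; tracts$lan.spanish <- lan[, 2]
    tracts$geometry <- I(lapply(seq_len(n_tr), function(i) {
      rect_poly(grid$col[i] - 1, grid$row[i] - 1, grid$col[i], grid$row[i])
    }))

    drow <- rows %/% f; dcol <- cols %/% f
    dg <- expand.grid(dcol = seq_len(dcol), drow = seq_len(drow))
    districts <- data.frame(
      id = sprintf("D%03d", seq_len(drow * dcol)),
      drow = dg$drow, dcol = dg$dcol
    )
    districts$geometry <- I(lapply(seq_len(nrow(districts)), function(i) {
      rect_poly((dg$dcol[i] - 1) * f, (dg$drow[i] - 1) * f,
                dg$dcol[i] * f, dg$drow[i] * f)
    }))
    cen <- t(vapply(districts$geometry, poly_centroid, numeric(2)))
    districts$cx <- cen[, 1]; districts$cy <- cen[, 2]
    tracts$district_id <- districts$id[(ceiling(tracts$row / f) - 1) * dcol +
                                         ceiling(tracts$col / f)]
    list(tracts = tracts, districts = districts)
  })
}

# district spatial effect: district-aggregated latent field, one queen
# smoothing pass on the district grid, standardized and rescaled
.district_effects <- function(tracts, districts, sd_target) {
  if (sd_target == 0) return(stats::setNames(rep(0, nrow(districts)), districts$id))
  agg <- tapply(tracts$latent, factor(tracts$district_id, levels = districts$id), mean)
  drow <- max(districts$drow); dcol <- max(districts$dcol)
  m <- matrix(NA_real_, drow, dcol)
  m[cbind(districts$drow, districts$dcol)] <- as.numeric(agg)
  m <- .grid_smooth(m, passes = 1)
  u <- m[cbind(districts$drow, districts$dcol)]
  u <- as.numeric(scale(u)) * sd_target
  stats::setNames(u, districts$id)
}

.draw_survivors <- function(n) {
  race <- sample(c("white", "black", "latin", "asian", "other"), n, TRUE,
                 prob = c(0.35, 0.30, 0.20, 0.10, 0.05))
  age <- sample(c("u18", "18.24", "25.44", "45.64", "o64"), n, TRUE,
                prob = c(0.25, 0.25, 0.30, 0.15, 0.05))
  female <- stats::rbinom(n, 1, 0.85)
  data.frame(vict.race = race, vict.age = age, vict.female = female)
}

# one-hot survivor columns named like the field's variable list
survivor_dummies <- function(events) {
  out <- data.frame(row.names = seq_len(nrow(events)))
  for (lev in c("white", "black", "latin", "asian", "other")) {
    out[[paste0("vict.", lev)]] <- as.integer(events$vict.race == lev)
  }
  out$vict.female <- as.integer(events$vict.female)
  for (lev in c("u18", "18.24", "25.44", "45.64", "o64")) {
    out[[paste0("vict.", lev)]] <- as.integer(events$vict.age == lev)
  }
  out
}

#' Generate synthetic event records
#'
#' Occurrence dates are uniform over the scenario's date range, optionally
#' heaped to the 1st/15th of the month (heaped events also receive a
#' positive delay shift, mimicking imprecise recall of long-delayed
#' reports). Delays follow
#' `log(1+delay) = mu + effects + u_district + eps` with a Pareto-tail
#' mixture, rounded to whole nonnegative days and capped. Under the
#' "point" regime events carry coordinates uniform in their tract; under
#' "district_centroid" every event sits on its district centroid.
#'
#' @param config A [scenario_config()].
#' @param areas Output of [generate_areas()] (regenerated if NULL).
#' @return list of class "synthetic_dataset": `events`, `tracts`,
#'   `districts`, `truth` (the config plus realized district effects).
#' @export
generate_events <- function(config, areas = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(areas)) areas <- generate_areas(config)
  tracts <- areas$tracts; districts <- areas$districts
  n <- config$n_events
  rows <- config$grid_tracts[1]; cols <- config$grid_tracts[2]
  yrs <- seq(as.POSIXlt(config$date_range[1])$year,
             as.POSIXlt(config$date_range[2])$year) + 1900L
  calendar <- build_holiday_calendar(yrs)
  with_local_seed(derive_seed(config$seed, 2L), {
    u <- .district_effects(tracts, districts, config$spatial_effect_sd)

    # location
    if (config$coordinate_regime == "point") {
      x <- stats::runif(n, 0, cols); y <- stats::runif(n, 0, rows)
      tcol <- pmin(cols, floor(x) + 1L); trow <- pmin(rows, floor(y) + 1L)
      tract_idx <- match(paste(trow, tcol), paste(tracts$row, tracts$col))
      tract_id <- tracts$id[tract_idx]
      district_id <- tracts$district_id[tract_idx]
    } else {
      didx <- sample.int(nrow(districts), n, replace = TRUE)
      district_id <- districts$id[didx]
      x <- districts$cx[didx]; y <- districts$cy[didx]
      tract_id <- NA_character_
    }

    # occurrence dates, heaped with probability heaping_prob
    span <- as.integer(config$date_range[2] - config$date_range[1])
    occ <- config$date_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
    heaped <- stats::rbinom(n, 1, config$heaping_prob) == 1
    if (any(heaped)) {
      lt <- as.POSIXlt(occ[heaped])
      lt$mday <- ifelse(lt$mday <= 8L, 1L, 15L)
      occ[heaped] <- as.Date(lt)
    }

    surv <- .draw_survivors(n)
    temp <- temporal_features(occ, calendar)
    feats <- cbind(survivor_dummies(surv), temp)

    lp <- rep(config$mu, n) + u[district_id]
    if (length(config$covariate_effects)) {
      unknown <- setdiff(names(config$covariate_effects), names(feats))
      if (length(unknown)) {
        stop("unknown covariate_effects name(s): ", paste(unknown, collapse = ", "))
      }
      for (nm in names(config$covariate_effects)) {
        lp <- lp + config$covariate_effects[[nm]] * feats[[nm]]
      }
    }
    lp <- lp + config$heaping_boost * heaped
    L <- lp + stats::rnorm(n, 0, config$sigma)
    in_tail <- stats::runif(n) < config$tail_mixture[1]
    L[in_tail] <- L[in_tail] + log(config$tail_mixture[2]) +
      stats::rexp(sum(in_tail)) / config$tail_alpha
    L <- pmin(L, log1p(config$delay_cap))
    delay <- pmax(0L, as.integer(round(expm1(L))))

    events <- data.frame(
      id = seq_len(n),
      occurrence_date = occ,
      report_date = occ + delay,
      district_id = district_id,
      tract_id = tract_id,
      lon = x, lat = y,
      surv,
      heaped = as.integer(heaped)
    )
    events$delay_days <- compute_delay(events$occurrence_date, events$report_date)
    events <- cbind(events, binarize_delay(events$delay_days))
    events$log_delay <- log_delay(events$delay_days)
    events <- cbind(events, temp)

    structure(list(events = events, tracts = tracts, districts = districts,
                   truth = list(config = config, district_effects = u)),
              class = "synthetic_dataset")
  })
}
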