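# Scenario configuration for the synthetic event generator.

#' Scenario configuration
#'
#' Defines a synthetic study scenario: a rows x cols grid of unit-square
#' census tracts, districts formed as square blocks of
#' `district_factor` x `district_factor` tracts, and the generative model
#' for reporting delays,
#'   log(1 + delay_i) = mu + sum(effects * covariates_i) + u_district(i) + eps_i,
#' with u a district-level spatial effect of marginal SD `spatial_effect_sd`
#' (driven by a smoothed latent field shared with the socio-economic tract
#' attributes), eps ~ N(0, sigma^2), plus a Pareto-tail mixture that
#' reproduces the heavy right tail of observed reporting delays, and
#' occurrence-date heaping onto the 1st/15th of the month.
#'
#' @param n_events Number of events (>= 1).
#' @param grid_tracts Integer c(rows, cols), both >= 2.
#' @param district_factor Block size; must divide both grid dimensions.
#' @param coordinate_regime "point" (block-level coordinates) or
#'   "district_centroid" (coordinates obfuscated to the district centroid).
#' @param spatial_effect_sd Marginal SD of the district effect on the
#'   log(1+delay) scale (>= 0).
#' @param covariate_effects Named numeric vector of additive effects on the
#'   log(1+delay) scale; names must be survivor dummies (e.g. "vict.u18",
#'   "vict.female") or temporal flags (e.g. "federal", "winter").
#' @param tail_mixture c(probability, scale): with this probability the
#'   delay is multiplied by a Pareto factor with the given minimum scale.
#' @param tail_alpha Pareto tail index of the mixture component.
#' @param heaping_prob Probability an occurrence date is heaped to the
#'   1st/15th of its month (imprecise recall).
#' @param heaping_boost Additive log(1+delay) shift for heaped events
#'   (imprecisely recalled events are reported late).
#' @param date_range Length-2 Date (or string) vector of occurrence dates.
#' @param mu Baseline mean of log(1+delay).
#' @param sigma SD of the event-level noise.
#' @param delay_cap Maximum delay in days.
#' @param seed Integer seed.
#' @return A validated list of class "scenario_config".
#' @export
scenario_config <- function(n_events = 1000,
                            grid_tracts = c(10L, 10L),
                            district_factor = 2L,
                            coordinate_regime = c("point", "district_centroid"),
                            spatial_effect_sd = 0,
                            covariate_effects = numeric(0),
                            tail_mixture = c(0.1, 3),
                            tail_alpha = 1.5,
                            heaping_prob = 0,
                            heaping_boost = log(3),
                            date_range = as.Date(c("2013-01-01", "2018-12-31")),
                            mu = log(4),
                            sigma = 1.2,
                            delay_cap = 1825,
                            seed = 1L) {
  coordinate_regime <- match.arg(coordinate_regime)
  grid_tracts <- as.integer(grid_tracts)
  district_factor <- as.integer(district_factor)
  if (n_events < 1) stop("n_events must be >= 1")
  if (length(grid_tracts) != 2 || any(grid_tracts < 2)) {
    stop("grid_tracts must be two integers >= 2")
  }
  if (district_factor < 1 || any(grid_tracts %% district_factor != 0)) {
    stop("district_factor must divide both grid dimensions exactly")
  }
  if (spatial_effect_sd < 0) stop("spatial_effect_sd must be >= 0")
  if (heaping_prob < 0 || heaping_prob > 1) stop("heaping_prob must be in [0, 1]")
  if (length(tail_mixture) != 2 || tail_mixture[1] < 0 || tail_mixture[1] > 1 ||
      tail_mixture[2] < 1) {
    stop("tail_mixture must be c(probability in [0,1], scale >= 1)")
  }
  if (length(covariate_effects) &&
      (is.null(names(covariate_effects)) || any(names(covariate_effects) == ""))) {
    stop("covariate_effects must be a named numeric vector")
  }
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || date_range[2] < date_range[1]) {
    stop("date_range must be two ordered dates")
  }
  cfg <- list(n_events = as.integer(n_events), grid_tracts = grid_tracts,
              district_factor = district_factor,
              coordinate_regime = coordinate_regime,
              spatial_effect_sd = spatial_effect_sd,
              covariate_effects = covariate_effects,
              tail_mixture = tail_mixture, tail_alpha = tail_alpha,
              heaping_prob = heaping_prob, heaping_boost = heaping_boost,
              date_range = date_range, mu = mu, sigma = sigma,
              delay_cap = delay_cap, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

#' Named scenario presets
#'
#' * `"null"` — no spatial effect, no covariate effects: district delays are
#'   exchangeable; used for calibration of the permutation tests.
#' * `"spatial"` — 100 districts, n = 3000, district effect SD 0.5 plus
#'   survivor/temporal effects; used for power and residual-autocorrelation
#'   analyses.
#' * `"la_style"` — the spatial preset with event point coordinates.
#' * `"ny_style"` — the spatial preset with coordinates obfuscated to
#'   district centroids.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scenario_config()].
#' @return A "scenario_config".
#' @export
scenario_preset <- function(name = c("null", "spatial", "la_style", "ny_style"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    null = list(n_events = 5928L, grid_tracts = c(8L, 38L), district_factor = 2L,
                coordinate_regime = "point", spatial_effect_sd = 0,
                covariate_effects = numeric(0), heaping_prob = 0),
    spatial = ,
    la_style = list(n_events = 3000L, grid_tracts = c(20L, 20L), district_factor = 2L,
                    coordinate_regime = "point", spatial_effect_sd = 0.5,
                    covariate_effects = c(vict.u18 = 0.8, vict.female = -0.4,
                                          federal = 1.0, winter = 0.3),
                    heaping_prob = 0.1),
    ny_style = list(n_events = 3000L, grid_tracts = c(20L, 20L), district_factor = 2L,
                    coordinate_regime = "district_centroid", spatial_effect_sd = 0.5,
                    covariate_effects = c(vict.u18 = 0.8, vict.female = -0.4,
                                          federal = 1.0, winter = 0.3),
                    heaping_prob = 0.1))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(scenario_config, args)
}
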