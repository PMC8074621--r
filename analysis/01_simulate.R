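#!/usr/bin/env Rscript
# Stage 1 — simulate the study scenarios.
#
# Generates the two headline scenarios: a spatially null city (no district
# effect, no covariate effects) and a spatially structured city (district
# effect SD 0.5 on the log(1+delay) scale plus survivor/holiday effects),
# and writes events as CSV and areas as GeoJSON under results/data/.

suppressPackageStartupMessages(library(reportlag))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20260930

for (preset in c("null", "spatial")) {
  ds <- generate_events(scenario_preset(preset, seed = seed))
  ev <- ds$events
  write_events_csv(ev, sprintf("results/data/events_%s.csv", preset))
  write_areas_geojson(ds$tracts, sprintf("results/data/tracts_%s.geojson", preset))
  write_areas_geojson(ds$districts, sprintf("results/data/districts_%s.geojson", preset))
  message(sprintf(
    "%-8s n=%d events, %d districts | median delay %.0f d, 99th pct %.0f d, %.1f%% reported after a month",
    preset, nrow(ev), nrow(ds$districts), median(ev$delay_days),
    quantile(ev$delay_days, 0.99), 100 * mean(ev$d_month == 0)))
}
message("wrote results/data/")
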