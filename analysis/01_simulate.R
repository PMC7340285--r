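#!/usr/bin/env Rscript
# Stage 1 -- synthesise the study system.
#
# Builds the 30 x 20 km study grid (1 km^2 cells), a 2004-2006 cruise
# calendar over the four modelled months (May, June, July, September),
# AR(1) climate index series with 0-3 month lags, and per-bin survey
# observations drawn from the documented ground truth: hurdle krill biomass
# with a log acoustic-volume offset and NB2 whale counts with a log
# survey-area offset. Writes bins, grid, climate and the serialised truth
# under results/simulate/.

library(whalekrill)

seed <- 1
outdir <- "results/simulate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

grid <- make_study_grid(c(30, 20), 1)
truth <- default_truth_spec(seed)
climate <- make_climate_table(2004:2008, ar = truth$climate$ar,
                              sd = truth$climate$sd, mean = truth$climate$mean,
                              seed = seed)
cruises <- make_cruises(2004:2008, c(5, 6, 7, 9), climate)
bins <- simulate_observations(grid, cruises, truth, seed = seed + 1)

write.csv(bins, file.path(outdir, "bins.csv"), row.names = FALSE)
write.csv(as.data.frame(grid), file.path(outdir, "grid.csv"), row.names = FALSE)
write.csv(climate, file.path(outdir, "climate.csv"), row.names = FALSE)
write.csv(cruises, file.path(outdir, "cruises.csv"), row.names = FALSE)
write_truth_spec(truth, file.path(outdir, "truth.json"))

cat(sprintf(
  "Simulated %d bins over %d cruises: %.1f%% krill zeros, %.1f%% blue and %.1f%% humpback presences.\n",
  nrow(bins), nrow(cruises), 100 * mean(bins$krill_biomass == 0),
  100 * mean(bins$blue_count > 0), 100 * mean(bins$humpback_count > 0)))
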