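#!/usr/bin/env Rscript
# Stage 2 -- krige the oceanographic surfaces.
#
# For every (cruise, variable, depth layer) triple, fits a variogram to the
# along-track (surface) or station (midwater) measurements, checks the four
# leave-one-out gates (>90% within the 95% band, >90% within 2 SD,
# %RMSE < 30, %ME < 2), falls back to second-order trend removal when a
# gate fails, and writes the prediction rasters plus a QC table.

library(whalekrill)

seed <- 1
outdir <- "results/krige"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

grid <- make_study_grid(c(30, 20), 1)
truth <- default_truth_spec(seed)
climate <- make_climate_table(2004:2008, ar = truth$climate$ar,
                              sd = truth$climate$sd, mean = truth$climate$mean,
                              seed = seed)
cruises <- make_cruises(2004:2008, c(5, 6, 7, 9), climate)
bins <- simulate_observations(grid, cruises, truth, seed = seed + 1)

inv <- surface_inventory(cruises$cruise_id)
qc_rows <- vector("list", nrow(inv))
for (i in seq_len(nrow(inv))) {
  col <- whalekrill:::field_column(inv$variable[i], inv$layer[i])
  cb <- bins[bins$cruise_id == inv$cruise_id[i], ]
  if (inv$layer[i] == "midwater") cb <- cb[seq(1, nrow(cb), by = 3), ]
  surf <- suppressWarnings(
    krige_surface(cb[, c("x", "y")], cb[[col]], grid[, c("x", "y")]))
  write_asc(surf$pred,
            grid, file.path(outdir, sprintf("surface_c%02d_%s_%s.asc",
                                            inv$cruise_id[i], inv$variable[i],
                                            inv$layer[i])))
  qc_rows[[i]] <- data.frame(inv[i, ], pct_within_ci95 = surf$qc$pct_within_ci95,
                             pct_within_2sd = surf$qc$pct_within_2sd,
                             pct_rmse = surf$qc$pct_rmse,
                             pct_me = surf$qc$pct_me, passed = surf$qc$passed,
                             detrended = surf$detrended)
}
qc <- do.call(rbind, qc_rows)
write.csv(qc, file.path(outdir, "qc_table.csv"), row.names = FALSE)

cat(sprintf("Kriged %d surfaces (%d cruises x 3 variables x 2 layers): %d passed QC, %d detrended.\n",
            nrow(qc), nrow(cruises), sum(qc$passed), sum(qc$detrended)))
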