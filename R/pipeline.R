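# End-to-end orchestration of the synthetic study analysis chain.

#' Default run configuration
#'
#' Aggregates every tunable constant of the chain: study extent, cruise
#' calendar, QC gates (90 / 90 / 30 / 2), selection alpha (0.05), CV
#' protocol (k = 10, 20 runs), Gi* weights (3 km self-inclusive band), FDR
#' alpha (0.05) and the master seed. Defaults give a small but complete
#' study (two years, four survey months).
#'
#' @param seed master seed.
#' @param years,months cruise calendar.
#' @param extent_km,cell_km study grid geometry.
#' @return named list (a run config).
#' @export
default_config <- function(seed = 1, years = 2004:2005, months = c(5, 6, 7, 9),
                           extent_km = c(30, 20), cell_km = 1) {
  list(seed = seed, years = years, months = months,
       extent_km = extent_km, cell_km = cell_km,
       qc_thresholds = c(ci95 = 90, sd2 = 90, rmse = 30, me = 2),
       selection_alpha = 0.05,
       cv = list(k = 10, runs = 20),
       gstar = list(scheme = "band", band = 3, self = TRUE),
       fdr_alpha = 0.05,
       run_cv = FALSE, run_selection = TRUE)
}

#' Validate a run configuration
#'
#' Checks every field and reports all violations at once.
#'
#' @param raw a config list (see [default_config()]).
#' @return the validated config; on any violation an error listing every
#'   offending field.
#' @export
validate_config <- function(raw) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(raw$seed) && length(raw$seed) == 1, "seed: single number required")
  chk(length(raw$years) >= 1, "years: at least one year")
  chk(all(raw$months %in% c(5, 6, 7, 9)), "months: must be within May/Jun/Jul/Sep")
  chk(length(raw$extent_km) %in% 1:2 && all(raw$extent_km > 1),
      "extent_km: extent must exceed one cell per axis")
  chk(raw$cell_km > 0, "cell_km: must be > 0")
  chk(all(raw$qc_thresholds > 0) &&
        all(c("ci95", "sd2", "rmse", "me") %in% names(raw$qc_thresholds)),
      "qc_thresholds: need positive ci95, sd2, rmse, me")
  chk(raw$selection_alpha > 0 && raw$selection_alpha < 1,
      "selection_alpha: must be in (0, 1)")
  chk(raw$cv$k >= 2, "cv$k: k-fold CV needs k >= 2")
  chk(raw$cv$runs >= 1, "cv$runs: need >= 1 run")
  chk(raw$gstar$band > 0, "gstar$band: band must be > 0")
  chk(raw$fdr_alpha > 0 && raw$fdr_alpha < 1, "fdr_alpha: must be in (0, 1)")
  if (length(errs)) stop_wk("invalid config:\n  ", paste(errs, collapse = "\n  "))
  raw
}

#' Kriged-surface inventory for a set of cruises
#'
#' The fixed bookkeeping of the kriging stage: one surface per (cruise,
#' variable, layer), i.e. cruises x 3 oceanographic variables x 2 depth
#' layers rows.
#'
#' @param cruise_ids vector of cruise identifiers.
#' @return data.frame with `cruise_id`, `variable`, `layer`.
#' @export
surface_inventory <- function(cruise_ids) {
  expand.grid(cruise_id = cruise_ids,
              variable = c("temperature", "salinity", "fluorescence"),
              layer = c("surface", "midwater"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

field_column <- function(variable, layer) {
  paste0(switch(variable, temperature = "temp", salinity = "sal",
                fluorescence = "fluor"),
         switch(layer, surface = "_surf", midwater = "_mid"))
}

#' Run the full analysis chain on a synthetic study
#'
#' Orchestrates: (1) synthesis of grid, climate, cruises and observations
#' from the ground truth; (2) kriging of each oceanographic variable per
#' cruise and layer with QC gating; (3) acoustic backscatter round-trip to
#' per-bin krill biomass; (4) covariate screening and backward stepwise
#' selection for the krill hurdle and whale NB models (optional, on by
#' default); (5) final fits with diagnostics (Vuong against ZINB for
#' whales, VIF, Moran's I); (6) per-cruise grid predictions; (7) Gi*
#' hotspot rasters with FDR masking and the persistence surface; (8)
#' global and local AB-ratio overlap. Deterministic given the config seed.
#'
#' @param config run configuration (see [default_config()]); validated
#'   before any computation.
#' @param truth optional `wk_truth` (defaults to [default_truth_spec()]
#'   seeded from the config).
#' @param outdir optional directory; when given, tables (CSV), reports
#'   (JSON) and rasters (ASCII grid) are written and checksummed into the
#'   manifest.
#' @return list of class `wk_run`: `grid`, `climate`, `cruises`, `bins`,
#'   `truth`, `surfaces`, `qc_table`, `biomass_check`, `fits`,
#'   `selection`, `predictions`, `hotspots`, `persistence`, `overlap`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), truth = NULL,
                         outdir = NULL) {
  config <- validate_config(config)
  if (is.null(truth)) truth <- default_truth_spec(seed = config$seed)
  manifest <- list()
  note <- function(stage, name, obj_path = NA_character_) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = name, path = obj_path,
      md5 = if (is.na(obj_path)) NA_character_ else
        unname(tools::md5sum(obj_path)))
  }
  seeds <- derive_seeds(config$seed, 8)

  ## stage 1: simulate ------------------------------------------------
  grid <- make_study_grid(config$extent_km, config$cell_km)
  climate <- make_climate_table(config$years, ar = truth$climate$ar,
                                sd = truth$climate$sd,
                                mean = truth$climate$mean, seed = seeds[1])
  cruises <- make_cruises(config$years, config$months, climate)
  bins <- simulate_observations(grid, cruises, truth, seed = seeds[2])
  note("simulate", "grid"); note("simulate", "climate")
  note("simulate", "cruises"); note("simulate", "bins")

  ## stage 2: krige ----------------------------------------------------
  inv <- surface_inventory(cruises$cruise_id)
  surfaces <- vector("list", nrow(inv))
  qc_rows <- vector("list", nrow(inv))
  for (i in seq_len(nrow(inv))) {
    col <- field_column(inv$variable[i], inv$layer[i])
    cb <- bins[bins$cruise_id == inv$cruise_id[i], ]
    # midwater variables are measured at stations (every 3rd bin), surface
    # variables continuously along-track
    if (inv$layer[i] == "midwater") cb <- cb[seq(1, nrow(cb), by = 3), ]
    surf <- krige_surface(cb[, c("x", "y")], cb[[col]], grid[, c("x", "y")],
                          thresholds = config$qc_thresholds)
    surfaces[[i]] <- surf
    qc_rows[[i]] <- data.frame(
      cruise_id = inv$cruise_id[i], variable = inv$variable[i],
      layer = inv$layer[i], pct_within_ci95 = surf$qc$pct_within_ci95,
      pct_within_2sd = surf$qc$pct_within_2sd, pct_rmse = surf$qc$pct_rmse,
      pct_me = surf$qc$pct_me, passed = surf$qc$passed,
      detrended = surf$detrended)
  }
  qc_table <- do.call(rbind, qc_rows)
  note("krige", paste0("surfaces (", nrow(inv), ")"))

  ## stage 3: biomass --------------------------------------------------
  # round-trip: invert per-bin biomass density to backscatter and convert
  # back through the length-frequency / cross-section arithmetic
  dens <- bins$krill_biomass / (bins$survey_area * 1e6) # g m^-2
  sA <- backscatter_from_biomass(dens)
  dens_back <- biomass_from_backscatter(sA)
  biomass_check <- max(abs(dens_back * bins$survey_area * 1e6 -
                             bins$krill_biomass))
  note("biomass", "round-trip check")

  ## stage 4: select ---------------------------------------------------
  covariates <- c(temp_surf = "oceanographic", temp_mid = "oceanographic",
                  sal_surf = "oceanographic", sal_mid = "oceanographic",
                  fluor_surf = "oceanographic", fluor_mid = "oceanographic",
                  depth = "bathymetric", contour_index = "bathymetric",
                  dist_mainland = "distance", dist_island = "distance",
                  dist_cordell = "distance", dist_200m = "distance",
                  soi = "climate", pdo = "climate", npgo = "climate",
                  ui = "climate")
  selection <- NULL
  if (isTRUE(config$run_selection)) {
    alpha <- config$selection_alpha
    sel_part <- function(response, family, offset) {
      sc <- screen_all(covariates, response, family, bins, offset = offset,
                       alpha = alpha)
      if (is.null(sc$design)) return(list(screens = sc$screens, step = NULL))
      list(screens = sc$screens,
           step = backward_stepwise(sc$design, bins, alpha = alpha))
    }
    bins$krill_present <- as.integer(bins$krill_biomass > 0)
    selection <- list(
      krill_zero = sel_part("krill_present", "logistic", NULL),
      krill_count = sel_part("krill_biomass", "ztnb", "acoustic_volume"),
      blue = sel_part("blue_count", "negbin", "survey_area"),
      humpback = sel_part("humpback_count", "negbin", "survey_area"))
  }
  note("select", "screens+stepwise")

  ## stage 5: fit ------------------------------------------------------
  design_of <- function(part, fallback_terms, response, family, offset) {
    if (!is.null(part$step)) return(part$step$final_design)
    design_spec(response, fallback_terms, offset = offset, family = family)
  }
  truth_terms <- function(part) part$terms
  bins$krill_present <- as.integer(bins$krill_biomass > 0)
  if (is.null(selection)) {
    zd <- design_spec("krill_present", truth_terms(truth$krill_presence),
                      family = "logistic")
    cd <- design_spec("krill_biomass", truth_terms(truth$krill_count),
                      offset = "acoustic_volume", family = "ztnb")
    bd <- design_spec("blue_count", truth_terms(truth$blue),
                      offset = "survey_area", family = "negbin")
    hd <- design_spec("humpback_count", truth_terms(truth$humpback),
                      offset = "survey_area", family = "negbin")
  } else {
    zd <- design_of(selection$krill_zero, truth_terms(truth$krill_presence),
                    "krill_present", "logistic", NULL)
    cd <- design_of(selection$krill_count, truth_terms(truth$krill_count),
                    "krill_biomass", "ztnb", "acoustic_volume")
    bd <- design_of(selection$blue, truth_terms(truth$blue),
                    "blue_count", "negbin", "survey_area")
    hd <- design_of(selection$humpback, truth_terms(truth$humpback),
                    "humpback_count", "negbin", "survey_area")
  }
  krill_fit <- fit_hurdle(zd, cd, bins)
  blue_fit <- fit_design(bd, bins)
  hump_fit <- fit_design(hd, bins)
  # zero-inflation check for the whale models (detection covariates in the
  # inflation part), adopted only on Vuong improvement
  zinb_zero <- design_spec("blue_count", list(term_spec("sea_state", "linear")),
                           family = "logistic")
  vuong <- lapply(list(blue = blue_fit, humpback = hump_fit), function(f) {
    zf <- tryCatch({
      zdn <- zinb_zero
      zdn$response <- f$design$response
      fit_zinb(f$design, zdn, bins)
    }, error = function(e) NULL)
    if (is.null(zf)) return(list(statistic = NA, p_value = NA,
                                 preferred = "a"))
    vuong_test(f, zf)
  })
  diag_fun <- function(f) {
    res <- (if (inherits(f, "wk_hurdle")) f$y else f$y) -
      predict_response(f, bins)
    morans_i(res, bins[, c("x", "y")], scheme = "band", band = 6)
  }
  fits <- list(krill = krill_fit, blue = blue_fit, humpback = hump_fit,
               vuong = vuong,
               moran = list(blue = diag_fun(blue_fit),
                            humpback = diag_fun(hump_fit)))
  if (isTRUE(config$run_cv)) {
    fits$cv <- list(
      krill = kfold_cv(list(zero = zd, count = cd), bins, k = config$cv$k,
                       runs = config$cv$runs, seed = seeds[5]),
      blue = kfold_cv(bd, bins, k = config$cv$k, runs = config$cv$runs,
                      seed = seeds[6]))
  }
  note("fit", "hurdle+negbin fits")

  ## stage 6: predict --------------------------------------------------
  predictions <- list(krill = list(), blue = list(), humpback = list())
  for (ci in seq_len(nrow(cruises))) {
    gdat <- grid
    for (i in which(inv$cruise_id == cruises$cruise_id[ci])) {
      gdat[[field_column(inv$variable[i], inv$layer[i])]] <- surfaces[[i]]$pred
    }
    for (cl in grep("_lag", names(cruises), value = TRUE)) {
      gdat[[cl]] <- cruises[[cl]][ci]
    }
    gdat$year <- cruises$year[ci]
    gdat$month <- cruises$month[ci]
    y <- cruises$year[ci]; m <- cruises$month[ci]
    predictions$krill[[ci]] <- predict_grid(krill_fit, gdat, "krill", y, m)
    predictions$blue[[ci]] <- predict_grid(blue_fit, gdat, "blue", y, m)
    predictions$humpback[[ci]] <- predict_grid(hump_fit, gdat, "humpback", y, m)
  }
  note("predict", paste0("rasters (", 3 * nrow(cruises), ")"))

  ## stage 7: hotspots -------------------------------------------------
  W <- gstar_weights(grid[, c("x", "y")], scheme = config$gstar$scheme,
                     band = config$gstar$band, self = config$gstar$self)
  hotspots <- lapply(predictions, function(rl) {
    lapply(rl, hotspot_raster, W = W, alpha = config$fdr_alpha)
  })
  persistence <- lapply(hotspots, persistence_sum)
  note("hotspots", "gi* rasters + persistence")

  ## stage 8: overlap --------------------------------------------------
  overlap <- list()
  for (sp in c("blue", "humpback")) {
    local_ab <- lapply(seq_len(nrow(cruises)), function(ci) {
      ab_ratio_local(predictions[[sp]][[ci]]$values,
                     predictions$krill[[ci]]$values)
    })
    global_by_year <- vapply(sort(unique(cruises$year)), function(y) {
      idx <- which(cruises$year == y)
      pred_y <- average_maps(predictions[[sp]][idx], "overall")
      prey_y <- average_maps(predictions$krill[idx], "overall")
      ab_ratio_global(pred_y$values, prey_y$values)
    }, 0)
    overlap[[sp]] <- list(
      local = local_ab,
      temporal = temporal_mean_sd(local_ab),
      global_by_year = stats::setNames(global_by_year,
                                       sort(unique(cruises$year))))
  }
  note("overlap", "ab ratios")

  out <- structure(list(
    grid = grid, climate = climate, cruises = cruises, bins = bins,
    truth = truth, surfaces = surfaces, surface_inventory = inv,
    qc_table = qc_table, biomass_check = biomass_check,
    fits = fits, selection = selection, predictions = predictions,
    hotspots = hotspots, persistence = persistence, overlap = overlap),
    class = "wk_run")
  if (!is.null(outdir)) {
    manifest <- write_run(out, outdir, manifest_sofar = manifest)
    out$manifest <- manifest
  } else {
    out$manifest <- do.call(rbind, manifest)
  }
  out
}

# Write pipeline artifacts as text files and return the checksummed manifest.
write_run <- function(run, outdir, manifest_sofar = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  put <- function(stage, name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, artifact = name, path = path,
      md5 = unname(tools::md5sum(path)))
  }
  put("simulate", "bins.csv", function(p) utils::write.csv(run$bins, p, row.names = FALSE))
  put("simulate", "grid.csv", function(p) utils::write.csv(as.data.frame(run$grid), p, row.names = FALSE))
  put("simulate", "climate.csv", function(p) utils::write.csv(run$climate, p, row.names = FALSE))
  put("simulate", "truth.json", function(p) write_truth_spec(run$truth, p))
  put("krige", "qc_table.csv", function(p) utils::write.csv(run$qc_table, p, row.names = FALSE))
  for (i in seq_len(nrow(run$surface_inventory))) {
    iv <- run$surface_inventory[i, ]
    nm <- sprintf("surface_c%02d_%s_%s.asc", iv$cruise_id, iv$variable, iv$layer)
    v <- run$surfaces[[i]]$pred
    put("krige", nm, function(p) write_asc(v, run$grid, p))
  }
  put("biomass", "biomass_check.json", function(p) {
    jsonlite::write_json(list(max_roundtrip_error_g = run$biomass_check), p,
                         auto_unbox = TRUE, digits = NA)
  })
  put("select", "selection.json", function(p) {
    sel <- if (is.null(run$selection)) list(skipped = TRUE) else {
      lapply(run$selection, function(part) {
        if (is.null(part$step)) return(list(final = NULL))
        list(final = design_formula_text(part$step$final_design),
             rule = part$step$rule, path = part$step$path)
      })
    }
    jsonlite::write_json(sel, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  put("fit", "fits.json", function(p) {
    enc <- function(f) list(coefficients = as.list(f$coefficients),
                            se = as.list(f$se), theta = f$theta,
                            aic = f$aic, bic = f$bic, logLik = f$logLik)
    jsonlite::write_json(list(
      krill_zero = enc(run$fits$krill$zero), krill_count = enc(run$fits$krill$count),
      blue = enc(run$fits$blue), humpback = enc(run$fits$humpback),
      vuong = run$fits$vuong), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  for (sp in names(run$predictions)) {
    for (ci in seq_along(run$predictions[[sp]])) {
      r <- run$predictions[[sp]][[ci]]
      nm <- sprintf("pred_%s_c%02d.asc", sp, ci)
      put("predict", nm, function(p) write_asc(r$values, run$grid, p))
    }
  }
  for (sp in names(run$persistence)) {
    nm <- sprintf("persistence_%s.asc", sp)
    v <- run$persistence[[sp]]$persistence
    put("hotspots", nm, function(p) write_asc(v, run$grid, p))
  }
  put("overlap", "ab_global.csv", function(p) {
    tab <- do.call(rbind, lapply(names(run$overlap), function(sp) {
      data.frame(species = sp,
                 year = names(run$overlap[[sp]]$global_by_year),
                 ab = as.numeric(run$overlap[[sp]]$global_by_year))
    }))
    utils::write.csv(tab, p, row.names = FALSE)
  })
  for (sp in names(run$overlap)) {
    nm <- sprintf("ab_mean_%s.asc", sp)
    v <- run$overlap[[sp]]$temporal$mean
    put("overlap", nm, function(p) write_asc(v, run$grid, p))
  }
  do.call(rbind, c(manifest_sofar, rows))
}
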