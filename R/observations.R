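#' Build the cruise calendar with lagged climate context
#'
#' Crosses study years with survey months (May, June, July, September --
#' April, August and October are not modelled) and attaches each climate
#' index at lags 0-3 months, mirroring how monthly index values are matched
#' to cruise timing.
#'
#' @param years integer study years.
#' @param months survey months (subset of `c(5, 6, 7, 9)`).
#' @param climate monthly climate table from [make_climate_table()]; must
#'   cover 3 months before the first cruise.
#' @return data.frame, one row per cruise: `cruise_id`, `year`, `month`,
#'   and `soi_lag0` ... `ui_lag3`.
#' @export
make_cruises <- function(years, months = c(5, 6, 7, 9), climate) {
  if (!all(months %in% c(5, 6, 7, 9))) {
    stop_wk("survey months are restricted to May, June, July, September")
  }
  cr <- expand.grid(month = months, year = years)[, c("year", "month")]
  cr <- cr[order(cr$year, cr$month), ]
  cr <- data.frame(cruise_id = seq_len(nrow(cr)), cr, row.names = NULL)
  for (idx in c("soi", "pdo", "npgo", "ui")) {
    for (lag in 0:3) {
      cr[[paste0(idx, "_lag", lag)]] <- mapply(function(y, m) {
        climate_at_lag(climate, y, m, idx, lag)
      }, cr$year, cr$month)
    }
  }
  cr
}

#' Detection-condition lookup for ESW and g(0)
#'
#' Maps Beaufort sea state to an effective strip half-width (km) and
#' trackline detection probability. Detection-function fitting is out of
#' scope; segment-specific ESW and g(0) are treated as supplied inputs, and
#' this table stands in for that supply in the synthetic study. Values
#' degrade with sea state, as detection does in practice.
#'
#' @return data.frame with `sea_state`, `esw`, `g0`.
#' @export
detection_lookup <- function() {
  data.frame(sea_state = 0:5,
             esw = c(2.4, 2.2, 2.0, 1.7, 1.4, 1.1),
             g0 = c(0.95, 0.92, 0.88, 0.82, 0.74, 0.65))
}

# Zero-truncated NB2 sampler via inverse-CDF on the conditional distribution.
rztnb <- function(n, mu, theta) {
  p0 <- stats::dnbinom(0, size = theta, mu = mu)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(pmin(u, 1 - 1e-16), size = theta, mu = mu)
}

#' Simulate survey observations on transect bins
#'
#' Lays east-west transects over the study grid, cuts them into 3 km bins
#' (discarding end-of-line fragments shorter than 1 km), samples the
#' oceanographic fields and static covariates at bin midpoints, and draws
#' krill and whale observations from the generating families the analysis
#' fits: krill presence ~ Bernoulli(logit^-1(X gamma)), positive krill
#' biomass (integer grams) ~ zero-truncated NB2 with mean
#' `exp(X beta + log(acoustic volume))`, whale counts ~ NB2 with mean
#' `exp(X beta + log(survey area))`.
#'
#' @param grid a `wk_grid`.
#' @param cruises cruise table from [make_cruises()].
#' @param truth a `wk_truth`.
#' @param seed integer seed; output is a pure function of
#'   (grid, cruises, truth, seed).
#' @param bin_km nominal bin length (km), default 3.
#' @param transect_spacing_km north-south spacing between transects.
#' @param strip_km surveyed strip width for whale effort (km); bin survey
#'   area = length x strip.
#' @param cell_volume_m3 constant volume of one acoustic integration cell;
#'   bin acoustic volume = cell count x this constant.
#' @param transect_length_km length of each transect; defaults to the grid's
#'   x extent minus 1 km so end-of-line discard is exercised.
#' @return data.frame of transect bins with effort, covariates (6
#'   oceanographic, 6 bathymetric/distance, 4 climate indices at lags 0-3),
#'   detection conditions with `esw`/`g0`, `krill_biomass`, `blue_count`,
#'   `humpback_count`.
#' @export
simulate_observations <- function(grid, cruises, truth, seed = truth$seed,
                                  bin_km = 3, transect_spacing_km = 4,
                                  strip_km = 5, cell_volume_m3 = 1000,
                                  transect_length_km = NULL) {
  extent <- attr(grid, "extent_km")
  cell_km <- attr(grid, "cell_km")
  if (is.null(transect_length_km)) transect_length_km <- extent[1] - 1
  stopifnot(transect_length_km <= extent[1])

  # transect template (same track every cruise, as for a fixed survey design)
  ty <- seq(transect_spacing_km / 2, extent[2] - transect_spacing_km / 4,
            by = transect_spacing_km)
  starts <- seq(0, transect_length_km - 1, by = bin_km)
  lens <- pmin(bin_km, transect_length_km - starts)
  keep <- lens >= 1 # end-of-line bins < 1 km are discarded
  template <- do.call(rbind, lapply(ty, function(y0) {
    data.frame(x = (starts + lens / 2)[keep], y = y0, length = lens[keep])
  }))

  seeds <- derive_seeds(seed, 3 + nrow(cruises))
  nfld <- length(truth$fields)

  bins_all <- vector("list", nrow(cruises))
  for (ci in seq_len(nrow(cruises))) {
    b <- template
    b$cruise_id <- cruises$cruise_id[ci]
    b$year <- cruises$year[ci]
    b$month <- cruises$month[ci]
    # nearest grid cell for static covariates
    ix <- pmin(pmax(ceiling(b$x / cell_km), 1), attr(grid, "nx"))
    iy <- pmin(pmax(ceiling(b$y / cell_km), 1), attr(grid, "ny"))
    b$cell_id <- (iy - 1L) * attr(grid, "nx") + ix
    for (v in c("depth", "contour_index", "dist_mainland", "dist_island",
                "dist_cordell", "dist_200m")) {
      b[[v]] <- grid[[v]][b$cell_id]
    }
    # oceanographic fields for this cruise, sampled at bin cells
    fseeds <- derive_seeds(seeds[3 + ci], nfld + 4)
    for (k in seq_len(nfld)) {
      fp <- truth$fields[[k]]
      fld <- simulate_field(grid, sill = fp$sill, range_km = fp$range_km,
                            nugget = fp$nugget, trend_coeffs = fp$trend_coeffs,
                            seed = fseeds[k])
      b[[names(truth$fields)[k]]] <- fld[b$cell_id]
    }
    # climate context replicated onto bins
    for (cl in grep("_lag", names(cruises), value = TRUE)) {
      b[[cl]] <- cruises[[cl]][ci]
    }
    # effort and detection conditions
    set.seed(fseeds[nfld + 1])
    b$acoustic_cell_count <- pmax(1L, as.integer(round(
      stats::rnorm(nrow(b), mean = 266, sd = 158))))
    b$acoustic_volume <- b$acoustic_cell_count * cell_volume_m3
    b$survey_area <- b$length * strip_km
    lk <- detection_lookup()
    b$sea_state <- sample(0:5, nrow(b), replace = TRUE,
                          prob = c(0.1, 0.25, 0.3, 0.2, 0.1, 0.05))
    b$swell <- sample(c("low", "medium", "high"), nrow(b), replace = TRUE,
                      prob = c(0.5, 0.35, 0.15))
    b$visibility <- sample(c("good", "fair", "poor"), nrow(b), replace = TRUE,
                           prob = c(0.6, 0.3, 0.1))
    b$esw <- lk$esw[match(b$sea_state, lk$sea_state)]
    b$g0 <- lk$g0[match(b$sea_state, lk$sea_state)]
    bins_all[[ci]] <- b
  }
  bins <- do.call(rbind, bins_all)
  bins$bin_id <- seq_len(nrow(bins))

  # responses drawn from the truth families
  set.seed(seeds[1])
  p_pres <- truth_expected(truth$krill_presence, bins, type = "prob")
  present <- stats::rbinom(nrow(bins), 1, p_pres)
  mu_krill <- truth_expected(truth$krill_count, bins,
                             offset = bins$acoustic_volume)
  krill <- integer(nrow(bins))
  if (any(present == 1)) {
    krill[present == 1] <- rztnb(sum(present), mu_krill[present == 1],
                                 truth$krill_count$theta)
  }
  bins$krill_biomass <- krill

  set.seed(seeds[2])
  mu_blue <- truth_expected(truth$blue, bins, offset = bins$survey_area)
  bins$blue_count <- stats::rnbinom(nrow(bins), size = truth$blue$theta,
                                    mu = mu_blue)
  set.seed(seeds[3])
  mu_hump <- truth_expected(truth$humpback, bins, offset = bins$survey_area)
  bins$humpback_count <- stats::rnbinom(nrow(bins), size = truth$humpback$theta,
                                        mu = mu_hump)

  front <- c("bin_id", "cruise_id", "year", "month", "x", "y", "cell_id",
             "length", "survey_area", "acoustic_cell_count", "acoustic_volume")
  bins <- bins[, c(front, setdiff(names(bins), front))]
  rownames(bins) <- NULL
  bins
}
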