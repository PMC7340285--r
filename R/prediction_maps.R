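# Gridded predictions, line-transect densities, temporal averaging and
# decile scaling.

#' Line-transect segment density
#'
#' `D = n / (2 * L * ESW * g0)` animals per km^2 for one track segment,
#' where ESW is the effective strip half-width (km) and g(0) the trackline
#' detection probability.
#'
#' @param n sightings (>= 0).
#' @param L segment length, km (> 0).
#' @param esw effective strip half-width, km (> 0).
#' @param g0 trackline detection probability in (0, 1].
#' @return animals / km^2 (vectorised).
#' @export
#' @examples
#' segment_density(2, 3, 1, 1) # 1/3
segment_density <- function(n, L, esw, g0) {
  if (any(L <= 0)) stop_wk("segment length must be > 0")
  if (any(esw <= 0)) stop_wk("esw must be > 0 (undefined correction)")
  if (any(g0 <= 0 | g0 > 1)) stop_wk("g0 must be in (0, 1]")
  if (any(n < 0)) stop_wk("sighting count must be >= 0")
  n / (2 * L * esw * g0)
}

#' A prediction raster for one species, year and month
#'
#' Thin container aligning a value vector with a study grid.
#'
#' @param values numeric per grid cell (NA = masked).
#' @param species,year,month metadata.
#' @return list of class `wk_raster`.
#' @export
prediction_raster <- function(values, species = NA, year = NA, month = NA) {
  structure(list(values = values, species = species, year = year,
                 month = month), class = "wk_raster")
}

#' Predict a fitted model onto the study grid
#'
#' Assembles the fit's covariate basis on grid cells (static covariates
#' plus the cruise's kriged oceanographic surfaces and climate context) and
#' applies the inverse link; hurdle fits combine as
#' `P(presence) * mu / (1 - NB(0; mu, theta))`. The effort offset is fixed
#' at one effort unit (log 1 = 0) so maps are per-unit-effort expected
#' abundance -- the decile maps are invariant to this choice. A missing
#' covariate column is an error naming the column.
#'
#' @param fit `wk_fit` or `wk_hurdle`.
#' @param grid_data data.frame: one row per grid cell carrying every model
#'   covariate (grid statics, kriged surfaces, climate lags, `year`).
#' @param species,year,month metadata for the returned raster.
#' @return `wk_raster`.
#' @export
predict_grid <- function(fit, grid_data, species = NA, year = NA, month = NA) {
  vals <- predict_response(fit, grid_data, effort = 1)
  prediction_raster(vals, species, year, month)
}

#' Average prediction rasters by calendar scheme
#'
#' `monthly`: mean of a given calendar month across years; `annual`: mean
#' across the surveyed months (May-September, August never modelled) within
#' each year; `overall`: monthly means within year first, then the mean
#' across years, which weights years equally regardless of how many months
#' each contributed. Provenance (contributing year-month pairs) is attached
#' to each averaged raster.
#'
#' @param rasters list of `wk_raster` with `year`/`month` set.
#' @param scheme `"monthly"`, `"annual"` or `"overall"`.
#' @return for `"monthly"`/`"annual"`: named list of `wk_raster`; for
#'   `"overall"`: a single `wk_raster`.
#' @export
average_maps <- function(rasters, scheme = c("monthly", "annual", "overall")) {
  scheme <- match.arg(scheme)
  if (!length(rasters)) stop_wk("empty raster set")
  yr <- vapply(rasters, function(r) r$year, 0)
  mo <- vapply(rasters, function(r) r$month, 0)
  vals <- lapply(rasters, function(r) r$values)
  cellmean <- function(idx) Reduce(`+`, vals[idx]) / length(idx)
  prov <- function(idx) data.frame(year = yr[idx], month = mo[idx])
  mk <- function(v, y, m, idx) {
    r <- prediction_raster(v, rasters[[1]]$species, y, m)
    attr(r, "provenance") <- prov(idx)
    r
  }
  if (scheme == "monthly") {
    out <- lapply(sort(unique(mo)), function(m) {
      idx <- which(mo == m)
      mk(cellmean(idx), NA, m, idx)
    })
    names(out) <- sort(unique(mo))
    out
  } else if (scheme == "annual") {
    out <- lapply(sort(unique(yr)), function(y) {
      idx <- which(yr == y)
      mk(cellmean(idx), y, NA, idx)
    })
    names(out) <- sort(unique(yr))
    out
  } else {
    years <- sort(unique(yr))
    per_year <- lapply(years, function(y) cellmean(which(yr == y)))
    mk(Reduce(`+`, per_year) / length(per_year), NA, NA, seq_along(rasters))
  }
}

#' Decile classification over a pooled raster set
#'
#' Class boundaries are the deciles of the pooled values of the full set
#' (per species and scheme), not per map, so classes are comparable across
#' time periods. Each cell gets its pooled-decile class 1-10; boundary ties
#' take the lower class. A constant pooled set collapses to a single class
#' with a warning.
#'
#' @param rasters list of `wk_raster` (or a single one).
#' @return list: `classes` (list of integer vectors parallel to the
#'   input), `breaks` (the 9 interior decile boundaries).
#' @export
decile_scale <- function(rasters) {
  if (inherits(rasters, "wk_raster")) rasters <- list(rasters)
  pooled <- unlist(lapply(rasters, function(r) r$values))
  pooled <- pooled[!is.na(pooled)]
  if (diff(range(pooled)) == 0) {
    warn_wk("constant pooled values: single decile class")
    return(list(classes = lapply(rasters, function(r)
      ifelse(is.na(r$values), NA_integer_, 1L)), breaks = rep(pooled[1], 9)))
  }
  breaks <- stats::quantile(pooled, probs = seq(0.1, 0.9, by = 0.1),
                            names = FALSE)
  classes <- lapply(rasters, function(r) {
    cl <- findInterval(r$values, breaks, left.open = TRUE) + 1L
    cl[is.na(r$values)] <- NA_integer_
    cl
  })
  list(classes = classes, breaks = breaks)
}
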