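#' Simulate a spatially autocorrelated field on the study grid
#'
#' Draws one realisation of a Gaussian random field with an isotropic
#' exponential covariance, `C(h) = (sill - nugget) * exp(-h / range_km)` plus
#' a nugget at h = 0, optionally on top of a linear/quadratic polynomial
#' trend in the cell coordinates. This is the generating model the kriging
#' stage assumes, so variogram estimation and kriging can be validated
#' against known parameters. The semivariogram convention is
#' `gamma(h) = nugget + (sill - nugget) * (1 - exp(-h / range_km))`, i.e.
#' `sill` is the total sill and `range_km` the exponential scale parameter.
#'
#' @param grid a `wk_grid` (or any data.frame with `x`, `y` columns).
#' @param sill total sill (variance at large lag); must be >= nugget >= 0.
#' @param range_km exponential range (scale) parameter, > 0.
#' @param nugget nugget variance.
#' @param trend_coeffs optional named numeric over any of
#'   `c("1","x","y","x2","y2","xy")` giving a deterministic trend added to
#'   the field; default a zero trend.
#' @param seed integer seed; the field is a pure function of (grid,
#'   parameters, seed).
#'
#' @return numeric vector of field values, one per grid row.
#' @export
simulate_field <- function(grid, sill, range_km, nugget = 0,
                           trend_coeffs = NULL, seed = 1) {
  if (nugget < 0 || sill < nugget) {
    stop_wk("need sill >= nugget >= 0 (got sill=", sill, ", nugget=", nugget, ")")
  }
  if (range_km <= 0) stop_wk("range_km must be > 0")
  n <- nrow(grid)
  mu <- eval_trend(trend_coeffs, grid$x, grid$y)
  psill <- sill - nugget
  if (sill <= 0) return(mu)

  set.seed(as.integer(seed))
  z <- rnorm(n)
  if (psill > 0) {
    D <- cross_dist(grid[, c("x", "y")], grid[, c("x", "y")])
    C <- psill * exp(-D / range_km)
    diag(C) <- diag(C) + nugget + 1e-10 * sill
    L <- tryCatch(chol(C), error = function(e) {
      stop_wk("covariance matrix is not positive definite: ", conditionMessage(e))
    })
    mu + drop(crossprod(L, z))
  } else {
    mu + sqrt(nugget) * z
  }
}

eval_trend <- function(coeffs, x, y) {
  out <- numeric(length(x))
  if (is.null(coeffs)) return(out)
  if (is.null(names(coeffs)) && length(coeffs) == 1L) names(coeffs) <- "1"
  basis <- list("1" = rep(1, length(x)), x = x, y = y,
                x2 = x^2, y2 = y^2, xy = x * y)
  bad <- setdiff(names(coeffs), names(basis))
  if (length(bad)) stop_wk("unknown trend terms: ", paste(bad, collapse = ", "))
  for (nm in names(coeffs)) out <- out + coeffs[[nm]] * basis[[nm]]
  out
}

#' Simulate a monthly climate-index series
#'
#' Generates a stationary AR(1) series emulating a basin-scale climate index
#' (SOI, PDO, NPGO, UI style), used to exercise lag selection in the
#' covariate screening protocol.
#'
#' @param n_months series length.
#' @param ar_coeff AR(1) coefficient, |ar_coeff| < 1.
#' @param sd innovation standard deviation (>= 0); 0 gives a constant series
#'   at `mean`.
#' @param seed integer seed.
#' @param mean series mean (default 0).
#' @return numeric vector of length `n_months`.
#' @export
simulate_climate <- function(n_months, ar_coeff = 0.5, sd = 1, seed = 1,
                             mean = 0) {
  if (abs(ar_coeff) >= 1) stop_wk("nonstationary ar_coeff: |", ar_coeff, "| >= 1")
  if (sd < 0) stop_wk("sd must be >= 0")
  if (sd == 0) return(rep(mean, n_months))
  set.seed(as.integer(seed))
  if (ar_coeff == 0) return(mean + rnorm(n_months, sd = sd))
  mean + as.numeric(stats::arima.sim(list(ar = ar_coeff), n_months, sd = sd))
}

#' Build a monthly climate table for a span of study years
#'
#' One AR(1) series per index (SOI, PDO, NPGO, UI), on a monthly calendar
#' covering the study years plus a 3-month head so that 0-3 month lags are
#' always available. Index-level means/SDs default to magnitudes in line with
#' published monthly index summaries (SOI/PDO/NPGO approximately mean-zero
#' unit-scale, UI positive and large).
#'
#' @param years integer vector of study years.
#' @param ar named numeric AR(1) coefficients per index.
#' @param sd,mean named numerics per index.
#' @param seed integer seed.
#' @return data.frame with `year`, `month` and one column per index.
#' @export
make_climate_table <- function(years,
                               ar = c(soi = 0.6, pdo = 0.8, npgo = 0.8, ui = 0.4),
                               sd = c(soi = 1.4, pdo = 0.7, npgo = 0.6, ui = 70),
                               mean = c(soi = 0, pdo = 0, npgo = 0, ui = 190),
                               seed = 1) {
  years <- sort(unique(as.integer(years)))
  # 3-month head before January of the first year
  cal <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  head_cal <- data.frame(year = min(years) - 1L, month = 10:12)
  cal <- rbind(head_cal, cal)
  seeds <- derive_seeds(seed, 4)
  out <- cal
  idx <- c("soi", "pdo", "npgo", "ui")
  for (k in seq_along(idx)) {
    nm <- idx[k]
    out[[nm]] <- simulate_climate(nrow(cal), ar_coeff = ar[[nm]], sd = sd[[nm]],
                                  seed = seeds[k], mean = mean[[nm]])
  }
  out
}

# Look up index value at a given lag (months before year/month).
climate_at_lag <- function(climate, year, month, index, lag) {
  m <- month - lag
  y <- year
  while (m < 1) { m <- m + 12; y <- y - 1 }
  row <- climate$year == y & climate$month == m
  if (!any(row)) stop_wk("climate table does not cover ", y, "-", m)
  climate[[index]][which(row)[1]]
}
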