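# Getis-Ord Gi* hotspot detection with FDR control, hotspot persistence,
# and AB-ratio trophic overlap.

#' Spatial weights for hotspot statistics
#'
#' Binary fixed-band or inverse-distance weights. Gi* conventionally
#' includes the focal cell (`self = TRUE`); Moran's I excludes it.
#' The default 3 km band matches the survey bin scale.
#'
#' @param coords two-column (x, y) matrix in km.
#' @param scheme `"band"` (binary, d <= band) or `"idw"`.
#' @param band band radius (km), > 0; also the idw cutoff.
#' @param self include the focal cell.
#' @return n x n symmetric weight matrix.
#' @export
gstar_weights <- function(coords, scheme = c("band", "idw"), band = 3,
                          self = TRUE) {
  scheme <- match.arg(scheme)
  if (band <= 0) stop_wk("band must be > 0")
  D <- cross_dist(coords, coords)
  W <- if (scheme == "band") (D <= band) * 1 else {
    w <- 1 / pmax(D, 1e-6)
    w[D > band] <- 0
    w
  }
  diag(W) <- if (self) 1 else 0
  W
}

#' Getis-Ord Gi* statistic per cell
#'
#' Local clustering statistic
#' `z_i = (sum_j w_ij x_j - xbar W_i) / (S sqrt((n sum_j w_ij^2 - W_i^2) / (n - 1)))`
#' with the global mean `xbar` and population standard deviation `S`;
#' significant positive z marks a cell whose neighbourhood carries
#' unusually high values (a hotspot). Two-sided normal p-values. A constant
#' raster has S = 0; z is defined as 0 everywhere and flagged.
#'
#' @param values numeric per cell (>= 9 cells).
#' @param coords cell midpoints (ignored when `W` supplied).
#' @param W optional precomputed weight matrix (self-inclusive).
#' @param ... passed to [gstar_weights()].
#' @return list: `z`, `p`, `constant` flag.
#' @export
getis_ord_gstar <- function(values, coords = NULL, W = NULL, ...) {
  values <- unname(as.numeric(values))
  n <- length(values)
  if (n < 9) stop_wk("need >= 9 cells")
  if (is.null(W)) W <- gstar_weights(coords, ...)
  dimnames(W) <- NULL
  xbar <- mean(values)
  S <- sqrt(mean(values^2) - xbar^2)
  if (S < 1e-12 * max(1, abs(xbar))) {
    return(list(z = rep(0, n), p = rep(1, n), constant = TRUE))
  }
  Wi <- rowSums(W)
  Wx <- drop(W %*% values)
  denom <- S * sqrt((n * rowSums(W^2) - Wi^2) / (n - 1))
  z <- (Wx - xbar * Wi) / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)), constant = FALSE)
}

#' Benjamini-Hochberg mask for one hotspot raster
#'
#' Adjusts the raster's p-values by the Benjamini-Hochberg step-up
#' procedure (applied per raster, across its unmasked cells) and masks to
#' cells that are both significant after adjustment and have positive z --
#' the hotspot definition.
#'
#' @param z,p Gi* z-scores and raw p-values.
#' @param alpha FDR level (default 0.05).
#' @return list: `mask` (logical), `p_adj`.
#' @export
fdr_mask <- function(z, p, alpha = 0.05) {
  if (!length(p)) return(list(mask = logical(0), p_adj = numeric(0)))
  p_adj <- stats::p.adjust(p, method = "BH")
  list(mask = p_adj < alpha & z > 0, p_adj = p_adj)
}

#' Hotspot raster for one month's predictions
#'
#' Runs Gi*, applies the FDR mask, and rescales the masked z-scores to
#' [0, 1] (min-max over masked cells only; a single masked cell maps to 1;
#' unmasked cells are 0), ready for persistence summation.
#'
#' @param raster `wk_raster` of predicted abundance.
#' @param coords cell midpoints.
#' @param W optional precomputed weights.
#' @param alpha FDR level.
#' @param ... passed to [gstar_weights()].
#' @return list of class `wk_hotspot`: `z`, `p`, `p_adj`, `mask`,
#'   `norm_z`, `year`, `month`.
#' @export
hotspot_raster <- function(raster, coords = NULL, W = NULL, alpha = 0.05, ...) {
  g <- getis_ord_gstar(raster$values, coords, W, ...)
  f <- fdr_mask(g$z, g$p, alpha)
  structure(list(z = g$z, p = g$p, p_adj = f$p_adj, mask = f$mask,
                 norm_z = rescale_masked_z(g$z, f$mask),
                 year = raster$year, month = raster$month,
                 constant = g$constant), class = "wk_hotspot")
}

# Min-max rescale of masked z to [0, 1]; 0 off-mask; single cell (or
# constant masked z) maps to 1.
rescale_masked_z <- function(z, mask) {
  out <- numeric(length(z))
  if (!any(mask)) return(out)
  zm <- z[mask]
  rng <- range(zm)
  out[mask] <- if (diff(rng) < 1e-12) 1 else (zm - rng[1]) / diff(rng)
  # the minimum masked cell still counts as a hotspot that month
  out
}

#' Hotspot persistence surface
#'
#' Cellwise sum of each month's normalised masked z-scores: a cell scores
#' in [0, 1] per month (1 = that month's strongest hotspot) so over M
#' months the surface ranges 0 to M -- with the full 39 modelled months,
#' 0 to 39. Months are exchangeable: permuting the raster list leaves the
#' surface unchanged.
#'
#' @param hotspot_rasters list of `wk_hotspot` on a common grid.
#' @return list: `persistence` (numeric per cell), `n_months`.
#' @export
persistence_sum <- function(hotspot_rasters) {
  if (!length(hotspot_rasters)) stop_wk("need >= 1 hotspot raster")
  len <- vapply(hotspot_rasters, function(h) length(h$norm_z), 0L)
  if (length(unique(len)) != 1) stop_wk("hotspot rasters on misaligned grids")
  list(persistence = Reduce(`+`, lapply(hotspot_rasters, function(h) h$norm_z)),
       n_months = length(hotspot_rasters))
}

#' Global AB-ratio trophic overlap
#'
#' `AB = mean((p_i - pbar) (b_i - bbar)) / (pbar * bbar)`: the spatial
#' covariance of predator and prey fields over the product of their means.
#' Positive values mean predators and prey co-occur beyond chance; zero, no
#' spatial association; negative, spatial segregation. Invariant to
#' rescaling either field by a positive constant.
#'
#' @param predator,prey non-negative value vectors on a common grid.
#' @return scalar AB ratio (`NA` with a warning if either mean is zero).
#' @export
ab_ratio_global <- function(predator, prey) {
  if (length(predator) != length(prey)) stop_wk("fields on misaligned grids")
  pbar <- mean(predator); bbar <- mean(prey)
  if (pbar == 0 || bbar == 0) {
    warn_wk("AB ratio undefined: a field has zero mean")
    return(NA_real_)
  }
  mean((predator - pbar) * (prey - bbar)) / (pbar * bbar)
}

#' Local AB ratio per cell
#'
#' `AB_i = (p_i - pbar)(b_i - bbar) / (pbar * bbar)` with means over the
#' same raster; the cellwise mean of the local ratios equals the global AB
#' ratio exactly.
#'
#' @inheritParams ab_ratio_global
#' @return numeric per cell.
#' @export
ab_ratio_local <- function(predator, prey) {
  if (length(predator) != length(prey)) stop_wk("fields on misaligned grids")
  pbar <- mean(predator); bbar <- mean(prey)
  if (pbar == 0 || bbar == 0) {
    warn_wk("AB ratio undefined: a field has zero mean")
    return(rep(NA_real_, length(predator)))
  }
  (predator - pbar) * (prey - bbar) / (pbar * bbar)
}

#' Temporal mean and SD of local AB rasters
#'
#' Cellwise mean and standard deviation (n - 1 denominator) across months.
#'
#' @param ab_list list of local-AB vectors on a common grid (>= 2 for SD).
#' @return list: `mean`, `sd` vectors.
#' @export
temporal_mean_sd <- function(ab_list) {
  if (length(ab_list) < 2) stop_wk("need >= 2 months for a temporal SD")
  M <- do.call(cbind, ab_list)
  list(mean = rowMeans(M), sd = apply(M, 1, stats::sd))
}
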