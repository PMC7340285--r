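#' Krill length-weight relationship
#'
#' Individual krill mass (g) as a function of body length (mm), from the
#' survey-derived polynomial `M(L) = 0.0002 L^2 - 0.0017 L + 0.005`. The
#' modelled length span is 8-30 mm (juvenile through adult *E. pacifica* and
#' *T. spinifera*); the polynomial itself is strictly positive for all
#' L >= 0 (its discriminant is negative, minimum 0.0013875 g at 4.25 mm).
#'
#' @param L length in mm, >= 0 (vectorised).
#' @return mass in g.
#' @export
#' @examples
#' length_weight(20) # 0.051 g
length_weight <- function(L) {
  if (any(L < 0)) stop_wk("length must be >= 0 mm")
  m <- 0.0002 * L^2 - 0.0017 * L + 0.005
  if (any(m <= 0)) stop_wk("non-positive mass for L = ",
                           paste(L[m <= 0], collapse = ", "))
  m
}

#' Length-frequency distribution of the krill assemblage
#'
#' @param lengths strictly increasing lengths (mm), by default within the
#'   8-30 mm modelled span.
#' @param proportions non-negative weights summing to 1 (tolerance 1e-9).
#' @param validate_span check the 8-30 mm span (disable for non-default use).
#' @return data.frame of class `wk_lf`.
#' @export
length_frequency <- function(lengths, proportions, validate_span = TRUE) {
  if (is.unsorted(lengths, strictly = TRUE)) {
    stop_wk("lengths must be strictly increasing")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop_wk("proportions must be non-negative and sum to 1")
  }
  if (validate_span && (min(lengths) < 8 || max(lengths) > 30)) {
    stop_wk("lengths outside the 8-30 mm modelled span")
  }
  structure(data.frame(length = lengths, proportion = proportions),
            class = c("wk_lf", "data.frame"))
}

#' Per-length backscattering cross-section table
#'
#' Individual backscattering cross-sections sigma_bs (m^2) per length class.
#' Scattering-model computation of these values is out of scope; any
#' positive table on the length grid is accepted. Cross-sections are
#' expected to grow with length; a decreasing table triggers an error unless
#' `monotone = FALSE`.
#'
#' @param lengths strictly increasing lengths (mm).
#' @param sigma_bs cross-sections (m^2), > 0.
#' @param monotone validate non-decreasing sigma_bs.
#' @return data.frame of class `wk_xs`.
#' @export
cross_section_table <- function(lengths, sigma_bs, monotone = TRUE) {
  if (is.unsorted(lengths, strictly = TRUE)) {
    stop_wk("lengths must be strictly increasing")
  }
  if (any(sigma_bs <= 0)) stop_wk("sigma_bs must be > 0")
  if (monotone && is.unsorted(sigma_bs)) {
    stop_wk("sigma_bs must be non-decreasing with length (set monotone = FALSE to override)")
  }
  structure(data.frame(length = lengths, sigma_bs = sigma_bs),
            class = c("wk_xs", "data.frame"))
}

#' Packaged default length grid, frequency and cross-sections
#'
#' A 1 mm length grid over 8-30 mm with a unimodal length-frequency
#' (centred near 17 mm) and cross-sections growing as L^2 around 1e-6 m^2 at
#' 20 mm -- magnitudes in line with euphausiid acoustic scattering at 120
#' kHz. These exercise the conversion arithmetic; real analyses supply their
#' own tables.
#' @return list with elements `lf` ([length_frequency()]) and `xs`
#'   ([cross_section_table()]).
#' @export
default_krill_acoustics <- function() {
  L <- 8:30
  w <- exp(-((L - 17) / 5)^2)
  list(lf = length_frequency(L, w / sum(w)),
       xs = cross_section_table(L, 1e-6 * (L / 20)^2))
}

#' Convert areal backscatter to krill biomass density
#'
#' Apportions the area backscattering coefficient to the length-frequency
#' distribution, divides by the frequency-weighted individual backscattering
#' cross-section to get numerical density, and multiplies by the
#' frequency-weighted individual mass:
#' `N = s_A / sum(f_l sigma_l)` (individuals / m^2),
#' `B = N * sum(f_l M(L_l))` (g / m^2). Linear in `s_A`.
#'
#' @param area_backscatter s_A in m^2 / m^2 (vectorised), >= 0.
#' @param lf a [length_frequency()].
#' @param xs a [cross_section_table()] on the same length grid.
#' @return biomass density in g / m^2.
#' @export
biomass_from_backscatter <- function(area_backscatter, lf = NULL, xs = NULL) {
  if (is.null(lf) || is.null(xs)) {
    d <- default_krill_acoustics()
    lf <- lf %||% d$lf
    xs <- xs %||% d$xs
  }
  if (!isTRUE(all.equal(lf$length, xs$length))) {
    stop_wk("length-frequency and cross-section tables must share a length grid")
  }
  if (any(area_backscatter < 0)) stop_wk("backscatter must be >= 0")
  denom <- sum(lf$proportion * xs$sigma_bs)
  if (denom <= 0) stop_wk("frequency-weighted cross-section is zero")
  mean_mass <- sum(lf$proportion * length_weight(lf$length))
  area_backscatter / denom * mean_mass
}

# Inverse of biomass_from_backscatter: the s_A that yields a given biomass
# density. Used by the synthetic generator so the conversion round-trips.
backscatter_from_biomass <- function(biomass_gm2, lf = NULL, xs = NULL) {
  if (is.null(lf) || is.null(xs)) {
    d <- default_krill_acoustics()
    lf <- lf %||% d$lf
    xs <- xs %||% d$xs
  }
  denom <- sum(lf$proportion * xs$sigma_bs)
  mean_mass <- sum(lf$proportion * length_weight(lf$length))
  biomass_gm2 / mean_mass * denom
}

#' Bin along-track acoustic samples into survey bins
#'
#' Integrated along-track samples (each covering a known track area and a
#' recorded count of sampled vertical cells) are grouped into `bin_km` bins
#' by along-track distance. Per bin: total biomass (g) summed as sample
#' density x sample area, effort as total sampled cell volume, and the log
#' volume offset used by the krill model. Bins with no sampled cells are
#' excluded with a message.
#'
#' @param samples data.frame with `distance_km` (along-track position),
#'   `s_A` (area backscattering coefficient), `cell_count`; optionally
#'   `sample_area_m2` (default 200 m width x sample spacing).
#' @param bin_km bin length, default 3.
#' @param cell_volume_m3 volume per sampled cell.
#' @param lf,xs length-frequency and cross-section tables (defaults from
#'   [default_krill_acoustics()]).
#' @return data.frame: `bin_index`, `biomass_gm2` (area-weighted mean
#'   density), `biomass_g` (total), `acoustic_cell_count`,
#'   `acoustic_volume`, `log_volume`.
#' @export
bin_acoustics <- function(samples, bin_km = 3, cell_volume_m3 = 1000,
                          lf = NULL, xs = NULL) {
  if (nrow(samples) == 0) {
    return(data.frame(bin_index = integer(), biomass_gm2 = numeric(),
                      biomass_g = numeric(), acoustic_cell_count = integer(),
                      acoustic_volume = numeric(), log_volume = numeric()))
  }
  if (is.null(samples$sample_area_m2)) {
    spacing <- if (nrow(samples) > 1) stats::median(diff(sort(samples$distance_km))) else bin_km
    samples$sample_area_m2 <- 200 * spacing * 1000
  }
  idx <- floor(samples$distance_km / bin_km)
  dens <- biomass_from_backscatter(samples$s_A, lf, xs)
  agg <- function(v, f) as.numeric(tapply(v, idx, f))
  out <- data.frame(
    bin_index = as.integer(names(tapply(idx, idx, length))),
    biomass_g = agg(dens * samples$sample_area_m2, sum),
    acoustic_cell_count = as.integer(agg(samples$cell_count, sum)),
    area_m2 = agg(samples$sample_area_m2, sum))
  out$biomass_gm2 <- out$biomass_g / out$area_m2
  out$acoustic_volume <- out$acoustic_cell_count * cell_volume_m3
  empty <- out$acoustic_cell_count == 0
  if (any(empty)) {
    message(sum(empty), " bin(s) with zero sampled cells excluded")
    out <- out[!empty, ]
  }
  out$log_volume <- log(out$acoustic_volume)
  out[, c("bin_index", "biomass_gm2", "biomass_g", "acoustic_cell_count",
          "acoustic_volume", "log_volume")]
}
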