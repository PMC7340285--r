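#' Ground-truth specification for the synthetic study
#'
#' Bundles everything the generator needs to draw observations from exactly
#' the model families the analysis fits: per-species coefficient vectors on a
#' stated term basis, the hurdle presence coefficients, NB2 dispersions,
#' spatial-field covariance parameters per oceanographic variable, climate
#' AR(1) parameters, and a seed. Serialising the truth with each dataset is
#' what makes parameter-recovery tests possible.
#'
#' @param krill_presence,krill_count,blue,humpback lists with elements
#'   `terms` (list of [term_spec()]) and `beta` (numeric: intercept followed
#'   by one coefficient per model-matrix column); count parts also carry
#'   `theta` (> 0).
#' @param fields named list per oceanographic covariate of
#'   `list(sill, range_km, nugget, trend_coeffs)`.
#' @param climate list with `ar`, `sd`, `mean` named vectors (see
#'   [make_climate_table()]).
#' @param seed integer master seed stored with the truth.
#' @return list of class `wk_truth`.
#' @export
truth_spec <- function(krill_presence, krill_count, blue, humpback,
                       fields, climate, seed = 1) {
  for (part in list(krill_count, blue, humpback)) {
    if (is.null(part$theta) || part$theta <= 0) stop_wk("count parts need theta > 0")
  }
  for (f in fields) {
    if (f$nugget < 0 || f$sill < f$nugget || f$range_km <= 0) {
      stop_wk("field parameters must satisfy sill >= nugget >= 0, range > 0")
    }
  }
  structure(list(krill_presence = krill_presence, krill_count = krill_count,
                 blue = blue, humpback = humpback, fields = fields,
                 climate = climate, seed = as.integer(seed)),
            class = "wk_truth")
}

#' Default ground truth
#'
#' The default basis gives each species one quadratic oceanographic term,
#' one distance term and one lagged climate term -- the smallest basis that
#' exercises every screening pathway (polynomial ladder, distance transform,
#' lag choice). Rates are calibrated to the study system this emulates:
#' roughly 17% krill zeros, ~3% blue whale and ~16% humpback presences per
#' 3 km bin, positive krill biomass on the order of 10^2-10^4 g per bin.
#'
#' @param seed integer seed stored with the truth.
#' @return `wk_truth`.
#' @export
default_truth_spec <- function(seed = 1) {
  truth_spec(
    # Quadratic responses are written on the raw covariate scale as
    # -a*(x - x0)^2 expanded; the displaced constant is absorbed into the
    # intercept. Intercepts are set so that, at typical covariate and effort
    # levels, zero/presence rates land near the study system's: ~17% krill
    # zeros, ~3% blue and ~16% humpback presences per bin.
    krill_presence = list(
      terms = list(term_spec("temp_mid", "quadratic"),
                   term_spec("dist_200m", "log"),
                   term_spec("soi", "linear", lag = 0)),
      beta = c(-46.35, 10, -0.5, -0.8, 0.35)),
    krill_count = list(
      terms = list(term_spec("fluor_surf", "quadratic"),
                   term_spec("dist_mainland", "linear"),
                   term_spec("ui", "linear", lag = 1)),
      beta = c(-8.87, 0.8, -0.04, -0.02, 0.0035),
      theta = 1.2),
    blue = list(
      terms = list(term_spec("temp_surf", "quadratic"),
                   term_spec("dist_200m", "linear"),
                   term_spec("ui", "linear", lag = 3)),
      beta = c(-19.12, 2.08, -0.08, -0.12, 0.003),
      theta = 0.7),
    humpback = list(
      terms = list(term_spec("temp_surf", "quadratic"),
                   term_spec("dist_200m", "linear"),
                   term_spec("soi", "linear", lag = 3)),
      beta = c(-13.71, 1.56, -0.06, -0.10, 0.20),
      theta = 0.9),
    fields = list(
      temp_surf = list(sill = 1.2, range_km = 8, nugget = 0.1,
                       trend_coeffs = c("1" = 13)),
      temp_mid = list(sill = 0.6, range_km = 10, nugget = 0.05,
                      trend_coeffs = c("1" = 10)),
      sal_surf = list(sill = 0.08, range_km = 12, nugget = 0.005,
                      trend_coeffs = c("1" = 33.4)),
      sal_mid = list(sill = 0.05, range_km = 12, nugget = 0.005,
                     trend_coeffs = c("1" = 33.6)),
      fluor_surf = list(sill = 2.5, range_km = 6, nugget = 0.2,
                        trend_coeffs = c("1" = 5)),
      fluor_mid = list(sill = 1.2, range_km = 6, nugget = 0.1,
                       trend_coeffs = c("1" = 3))),
    climate = list(ar = c(soi = 0.6, pdo = 0.8, npgo = 0.8, ui = 0.4),
                   sd = c(soi = 1.4, pdo = 0.7, npgo = 0.6, ui = 70),
                   mean = c(soi = 0, pdo = 0, npgo = 0, ui = 190)),
    seed = seed)
}

#' Serialise / read a truth specification as JSON
#' @param truth a `wk_truth`.
#' @param path file path.
#' @export
write_truth_spec <- function(truth, path) {
  ser <- truth
  ser$krill_presence <- serialise_part(truth$krill_presence)
  ser$krill_count <- serialise_part(truth$krill_count)
  ser$blue <- serialise_part(truth$blue)
  ser$humpback <- serialise_part(truth$humpback)
  jsonlite::write_json(unclass(ser), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_spec
#' @export
read_truth_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  de <- function(p) {
    terms <- lapply(seq_len(nrow(p$terms)), function(i) {
      term_spec(p$terms$covariate[i], p$terms$transform[i],
                lag = if (is.na(p$terms$lag[i])) NA else p$terms$lag[i])
    })
    out <- list(terms = terms, beta = p$beta)
    if (!is.null(p$theta)) out$theta <- p$theta
    out
  }
  truth_spec(de(raw$krill_presence), de(raw$krill_count), de(raw$blue),
             de(raw$humpback),
             fields = lapply(raw$fields, function(f) {
               f$trend_coeffs <- unlist(f$trend_coeffs)
               f
             }),
             climate = lapply(raw$climate, unlist), seed = raw$seed)
}

serialise_part <- function(p) {
  p$terms <- do.call(rbind, lapply(p$terms, function(tm) {
    data.frame(covariate = tm$covariate, transform = tm$transform,
               lag = tm$lag, by_year = tm$by_year)
  }))
  p
}

# Linear predictor of one truth part on a bins table (no offset).
truth_linpred <- function(part, bins) {
  des <- design_spec(".truth", part$terms, family = "negbin")
  X <- build_model_matrix(des, bins)
  if (length(part$beta) != ncol(X)) {
    stop_wk("truth beta has length ", length(part$beta),
            " but the term basis produces ", ncol(X), " columns")
  }
  drop(X %*% part$beta)
}

#' Expected response under the truth
#'
#' Per-bin expected values implied by a truth coefficient part: presence
#' probability for the logistic part, NB mean `exp(X beta + log(offset))`
#' for count parts.
#'
#' @param part one of the coefficient parts of a `wk_truth`.
#' @param bins bins data.frame.
#' @param type `"mean"` (count scale) or `"prob"` (presence probability).
#' @param offset optional effort vector (raw scale, logged internally).
#' @return numeric vector.
#' @export
truth_expected <- function(part, bins, type = c("mean", "prob"), offset = NULL) {
  type <- match.arg(type)
  eta <- truth_linpred(part, bins)
  if (!is.null(offset)) eta <- eta + log(offset)
  if (type == "prob") stats::plogis(eta) else exp(eta)
}
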