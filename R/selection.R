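# Covariate-selection protocol: univariate functional-form and lag
# screening, backward stepwise elimination under the AIC decrease rule,
# the delta-AIC-2 / BIC final-model rule, and year-interaction testing.

# Block likelihood-ratio p of a design against intercept(+offset)-only.
block_lrt_p <- function(design, data, fit = NULL) {
  if (is.null(fit)) fit <- fit_design(design, data)
  null_design <- design
  null_design$terms <- list()
  f0 <- fit_design(null_design, data)
  df <- fit$df - f0$df
  stat <- 2 * (fit$logLik - f0$logLik)
  list(p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       stat = stat, df = df, fit = fit)
}

#' Univariate screening of one covariate
#'
#' Selects the functional form each covariate enters the full model with,
#' by covariate class: oceanographic and bathymetric covariates climb the
#' polynomial ladder (linear, quadratic, cubic, quartic) and enter at the
#' highest order whose top term is significant (p < alpha) in a univariate
#' fit; distance covariates try linear, quadratic, log and inverse-log
#' transforms and enter with the most significant (block LRT); climate
#' indices try lags 0-3 months (each at the polynomial ladder, default up
#' to quadratic) and enter at the most significant lag. A covariate with no
#' significant candidate is excluded.
#'
#' @param covariate covariate name (for climate, the index name without the
#'   lag suffix).
#' @param class `"oceanographic"`, `"bathymetric"`, `"distance"` or
#'   `"climate"`.
#' @param response,family,offset passed to [design_spec()] for the
#'   univariate fits.
#' @param data observations.
#' @param alpha significance level (default 0.05).
#' @param max_order top polynomial order for ladder classes (default 4; 2
#'   for climate).
#' @return list of class `wk_screen`: `covariate`, `class`, `included`,
#'   `term` (a [term_spec()] or NULL), `candidates` (data.frame of form,
#'   lag, p, aic).
#' @export
screen_variable <- function(covariate, class, response, family, data,
                            offset = NULL, alpha = 0.05,
                            max_order = if (class == "climate") 2 else 4) {
  class <- match.arg(class, c("oceanographic", "bathymetric", "distance",
                              "climate"))
  ladder <- c("linear", "quadratic", "cubic", "quartic")
  cand <- data.frame(form = character(), lag = integer(), p = numeric(),
                     aic = numeric())
  try_fit <- function(tm) {
    des <- design_spec(response, list(tm), offset = offset, family = family)
    tryCatch(fit_design(des, data), error = function(e) NULL)
  }
  add_cand <- function(form, lag, p, aic) {
    rbind(cand, data.frame(form = form, lag = lag, p = p, aic = aic))
  }
  chosen <- NULL
  if (class %in% c("oceanographic", "bathymetric")) {
    for (ord in seq_len(max_order)) {
      tm <- term_spec(covariate, ladder[ord])
      f <- try_fit(tm)
      if (is.null(f)) next
      p_top <- utils::tail(f$p_values, 1) # Wald p of the top-order term
      cand <- add_cand(ladder[ord], NA, p_top, f$aic)
      if (isTRUE(p_top < alpha)) chosen <- tm # highest significant order wins
    }
  } else if (class == "distance") {
    best_p <- Inf
    for (form in c("linear", "quadratic", "log", "invlog")) {
      tm <- term_spec(covariate, form)
      f <- try_fit(tm)
      if (is.null(f)) next
      des <- design_spec(response, list(tm), offset = offset, family = family)
      p_blk <- block_lrt_p(des, data, f)$p
      cand <- add_cand(form, NA, p_blk, f$aic)
      if (isTRUE(p_blk < alpha) && p_blk < best_p) { chosen <- tm; best_p <- p_blk }
    }
  } else { # climate: pick the most significant lag
    best_p <- Inf
    for (lag in 0:3) {
      lag_best <- NULL
      for (ord in seq_len(max_order)) {
        tm <- term_spec(covariate, ladder[ord], lag = lag)
        f <- try_fit(tm)
        if (is.null(f)) next
        p_top <- utils::tail(f$p_values, 1)
        cand <- add_cand(ladder[ord], lag, p_top, f$aic)
        if (isTRUE(p_top < alpha)) lag_best <- tm
      }
      if (!is.null(lag_best)) {
        des <- design_spec(response, list(lag_best), offset = offset,
                           family = family)
        p_blk <- block_lrt_p(des, data)$p
        if (isTRUE(p_blk < best_p)) { chosen <- lag_best; best_p <- p_blk }
      }
    }
  }
  structure(list(covariate = covariate, class = class,
                 included = !is.null(chosen), term = chosen,
                 candidates = cand), class = "wk_screen")
}

#' Screen a covariate dictionary and assemble the full design
#'
#' @param covariates named character vector mapping covariate name to
#'   class (as in [screen_variable()]).
#' @param response,family,offset,data,alpha as in [screen_variable()].
#' @return list: `design` (a `wk_design` over the included covariates, or
#'   NULL if none), `screens` (list of `wk_screen`).
#' @export
screen_all <- function(covariates, response, family, data, offset = NULL,
                       alpha = 0.05) {
  screens <- lapply(names(covariates), function(cv) {
    screen_variable(cv, covariates[[cv]], response, family, data,
                    offset = offset, alpha = alpha)
  })
  names(screens) <- names(covariates)
  terms <- Filter(Negate(is.null), lapply(screens, function(s) s$term))
  design <- if (length(terms)) {
    design_spec(response, unname(terms), offset = offset, family = family)
  } else NULL
  list(design = design, screens = screens)
}

# Droppable-unit p-values per term: Wald p of the top-order column of each
# polynomial/transform term (interaction blocks are handled in the
# year-interaction stage, not here).
droppable_pvalues <- function(fit) {
  term_of <- attr(fit$X, "term_of")
  terms <- fit$design$terms
  vapply(seq_along(terms), function(i) {
    cols <- which(term_of == i)
    utils::tail(fit$p_values[cols], 1)
  }, 0)
}

#' Manual-style backward stepwise elimination
#'
#' From the screened full model, repeatedly drops the least-significant
#' droppable unit -- the top order of a polynomial term (marginality:
#' lower orders are never removed while a higher order remains) or a whole
#' single-column term -- refits, and requires AIC to decrease at each
#' step; elimination stops when every term is significant (p < alpha). If
#' no candidate drop decreases AIC while non-significant terms remain, the
#' conflict is recorded and the least-significant term is removed anyway
#' (flagged `forced` in the path), so elimination always reaches a fully
#' significant model; the closing AIC/BIC rule arbitrates between the
#' conflicting models. The final model is chosen over all models on the
#' path: the lowest-AIC model if it beats the runner-up by more than 2
#' AIC units, otherwise the lowest-BIC model among those within 2 AIC
#' units of the best -- which is what discards a marginally
#' non-significant term whose removal nudged AIC up by less than its
#' parameter penalty.
#'
#' @param full_design the screened starting `wk_design`.
#' @param data observations.
#' @param alpha retention significance level.
#' @return list of class `wk_steppath`: `path` (data.frame: step, model
#'   label, aic, bic, dropped, n_terms), `designs`, `final_design`,
#'   `final_fit`, `rule` (`"dAIC>2"` or `"BIC tie-break"`), `deadlock`
#'   (term labels, if any).
#' @export
backward_stepwise <- function(full_design, data, alpha = 0.05) {
  current <- full_design
  fit <- fit_design(current, data)
  designs <- list(current)
  fits <- list(fit)
  path <- data.frame(step = 0L, model = design_formula_text(current),
                     aic = fit$aic, bic = fit$bic, dropped = NA_character_,
                     forced = FALSE, n_terms = length(current$terms))
  deadlock <- character()
  step <- 0L
  repeat {
    if (!length(current$terms)) break
    dp <- droppable_pvalues(fit)
    labels <- vapply(current$terms, term_label, "")
    nonsig <- which(dp >= alpha)
    if (!length(nonsig)) break
    # least significant first; exact ties broken by AIC improvement is
    # implicit in the acceptance scan below, then lexicographic
    ord <- nonsig[order(-dp[nonsig], labels[nonsig])]
    take <- NULL
    for (i in ord) {
      cand_design <- drop_top_order(current, i)
      cand_fit <- tryCatch(fit_design(cand_design, data),
                           error = function(e) NULL)
      if (is.null(cand_fit)) next
      if (cand_fit$aic < fit$aic) {
        take <- list(i = i, design = cand_design, fit = cand_fit,
                     forced = FALSE)
        break
      }
      if (is.null(take)) { # fall back to the least-significant drop
        take <- list(i = i, design = cand_design, fit = cand_fit,
                     forced = TRUE)
      }
    }
    if (is.null(take)) break
    if (take$forced) {
      deadlock <- union(deadlock, labels[nonsig])
      warn_wk("no drop decreases AIC among non-significant terms {",
              paste(labels[nonsig], collapse = ", "),
              "}; removing the least significant anyway")
    }
    step <- step + 1L
    dropped_lab <- paste0(labels[take$i], " (",
                          current$terms[[take$i]]$transform, ")")
    current <- take$design
    fit <- take$fit
    designs[[length(designs) + 1L]] <- current
    fits[[length(fits) + 1L]] <- fit
    path <- rbind(path, data.frame(
      step = step, model = design_formula_text(current),
      aic = fit$aic, bic = fit$bic, dropped = dropped_lab,
      forced = take$forced, n_terms = length(current$terms)))
  }
  sel <- apply_aic_bic_rule(path$aic, path$bic)
  final <- sel$index
  rule <- sel$rule
  structure(list(path = path, designs = designs,
                 final_design = designs[[final]], final_fit = fits[[final]],
                 rule = rule, deadlock = deadlock),
            class = "wk_steppath")
}

#' Final-model decision rule over a stepwise path
#'
#' Applies the closing rule of the selection protocol to the candidate
#' models' AIC/BIC values: take the lowest-AIC model when it beats the
#' runner-up by more than 2 units; otherwise take the lowest-BIC model
#' among all candidates within 2 AIC units of the best.
#'
#' @param aic,bic numeric vectors over the candidate models.
#' @return list: `index` (selected model), `rule` (`"dAIC>2"` or
#'   `"BIC tie-break"`).
#' @export
apply_aic_bic_rule <- function(aic, bic) {
  stopifnot(length(aic) == length(bic), length(aic) >= 1)
  best <- which.min(aic)
  gap <- if (length(aic) > 1) sort(aic)[2] - aic[best] else Inf
  if (gap > 2) {
    list(index = best, rule = "dAIC>2")
  } else {
    within <- which(aic - aic[best] <= 2)
    list(index = within[which.min(bic[within])], rule = "BIC tie-break")
  }
}

#' @export
print.wk_steppath <- function(x, ...) {
  cat("<wk_steppath>", nrow(x$path), "model(s); rule:", x$rule, "\n")
  print(x$path[, c("step", "aic", "bic", "dropped")], row.names = FALSE)
  cat("final:", design_formula_text(x$final_design), "\n")
  if (length(x$deadlock)) cat("deadlock terms:", paste(x$deadlock, collapse = ", "), "\n")
  invisible(x)
}

#' Test year interactions for static features
#'
#' For each candidate static feature present in the base model, refits
#' with the feature's columns crossed with a categorical year factor and
#' tests improvement by likelihood ratio; interactions are retained where
#' the LRT is significant (p < alpha) and AIC improves. For hurdle models
#' the candidate must appear in both parts (testing proceeds per part).
#' A year level with fewer than 2 observations skips the test with a
#' warning.
#'
#' @param base_design the selected `wk_design`.
#' @param static_vars candidate features, subset of the bathymetric/
#'   distance covariates.
#' @param data observations.
#' @param alpha LRT significance level.
#' @return list of class `wk_yearint`: `table` (var, lrt_stat, df, p,
#'   aic_base, aic_int, retained), `final_design`, `final_fit`.
#' @export
year_interaction_test <- function(base_design, static_vars, data,
                                  alpha = 0.05) {
  labels <- vapply(base_design$terms, term_label, "")
  missing_v <- setdiff(static_vars, labels)
  if (length(missing_v)) {
    stop_wk("base model lacks static variable(s): ",
            paste(missing_v, collapse = ", "))
  }
  yr_counts <- table(data$year)
  if (any(yr_counts < 2)) {
    warn_wk("year level(s) with < 2 observations: ",
            paste(names(yr_counts)[yr_counts < 2], collapse = ", "),
            "; interactions skipped")
    return(structure(list(table = NULL, final_design = base_design,
                          final_fit = fit_design(base_design, data)),
                     class = "wk_yearint"))
  }
  base_fit <- fit_design(base_design, data)
  rows <- list()
  current <- base_design
  current_fit <- base_fit
  for (v in static_vars) {
    i <- which(labels == v)
    cand <- current
    cand$terms[[i]]$by_year <- TRUE
    cand_fit <- tryCatch(fit_design(cand, data), error = function(e) NULL)
    if (is.null(cand_fit)) {
      rows[[v]] <- data.frame(var = v, lrt_stat = NA, df = NA, p = NA,
                              aic_base = current_fit$aic, aic_int = NA,
                              retained = FALSE)
      next
    }
    stat <- 2 * (cand_fit$logLik - current_fit$logLik)
    df <- cand_fit$df - current_fit$df
    p <- stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
    keep <- p < alpha && cand_fit$aic < current_fit$aic
    rows[[v]] <- data.frame(var = v, lrt_stat = stat, df = df, p = p,
                            aic_base = current_fit$aic, aic_int = cand_fit$aic,
                            retained = keep)
    if (keep) {
      current <- cand
      current_fit <- cand_fit
    }
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 final_design = current, final_fit = current_fit),
            class = "wk_yearint")
}
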