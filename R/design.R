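#' Model term and design specifications
#'
#' A design specification names a response, an ordered list of covariate
#' terms, an optional effort offset, and a model family. Terms carry the
#' functional form used throughout the covariate-selection protocol:
#' polynomial ladders (linear through quartic, always including all lower
#' orders), a log transform `log(1 + x)` and an inverse-log transform
#' `1 / (1 + log(1 + x))` for distance covariates, an optional 0-3 month lag
#' for climate indices, and an optional interaction-with-year flag.
#'
#' @param covariate covariate (column) name; lagged climate covariates are
#'   stored as `<name>_lag<k>` columns and addressed via `lag`.
#' @param transform one of `"linear"`, `"quadratic"`, `"cubic"`, `"quartic"`,
#'   `"log"`, `"invlog"`.
#' @param lag optional integer 0-3 for climate indices; `NA` otherwise.
#' @param by_year if `TRUE`, the term's columns are crossed with a
#'   categorical year factor (year main effects are added automatically).
#' @return A list of class `wk_term`.
#' @export
term_spec <- function(covariate, transform = "linear", lag = NA, by_year = FALSE) {
  transform <- match.arg(transform,
                         c("linear", "quadratic", "cubic", "quartic", "log", "invlog"))
  if (!is.na(lag) && !(lag %in% 0:3)) stop_wk("lag must be in 0:3 or NA")
  structure(list(covariate = covariate, transform = transform,
                 lag = if (is.na(lag)) NA_integer_ else as.integer(lag),
                 by_year = isTRUE(by_year)),
            class = "wk_term")
}

#' @rdname term_spec
#' @param response response column name.
#' @param terms list of `wk_term` objects (or a single one).
#' @param offset optional name of an effort column; the offset enters the
#'   linear predictor as `log(offset)` with coefficient fixed at 1.
#' @param family one of `"logistic"`, `"negbin"`, `"ztnb"`, `"zinb"`.
#' @export
design_spec <- function(response, terms, offset = NULL,
                        family = c("negbin", "logistic", "ztnb", "zinb")) {
  family <- match.arg(family)
  if (inherits(terms, "wk_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, TRUE, "wk_term")))
  covs <- vapply(terms, term_label, "")
  if (anyDuplicated(covs)) stop_wk("each covariate may appear once per design")
  structure(list(response = response, terms = terms, offset = offset,
                 family = family),
            class = "wk_design")
}

term_label <- function(tm) {
  if (is.na(tm$lag)) tm$covariate else paste0(tm$covariate, "_lag", tm$lag)
}

poly_order <- function(transform) {
  switch(transform, linear = 1L, quadratic = 2L, cubic = 3L, quartic = 4L, NA_integer_)
}

# Columns produced by one term (before year interaction).
term_columns <- function(tm, data) {
  col <- term_label(tm)
  if (!col %in% names(data)) {
    stop_wk("covariate '", col, "' not found in data")
  }
  x <- data[[col]]
  ord <- poly_order(tm$transform)
  if (!is.na(ord)) {
    m <- vapply(seq_len(ord), function(k) x^k, numeric(length(x)))
    m <- matrix(m, ncol = ord)
    colnames(m) <- if (ord == 1) col else
      c(col, paste0(col, "_", 2:ord))
  } else if (tm$transform == "log") {
    if (any(x < 0)) stop_wk("log transform needs non-negative '", col, "'")
    m <- matrix(log1p(x), ncol = 1, dimnames = list(NULL, paste0("log_", col)))
  } else { # invlog
    if (any(x < 0)) stop_wk("invlog transform needs non-negative '", col, "'")
    m <- matrix(1 / (1 + log1p(x)), ncol = 1,
                dimnames = list(NULL, paste0("invlog_", col)))
  }
  m
}

#' Build the model matrix for a design
#'
#' Assembles the intercept, each term's transformed columns, year main
#' effects and year-interaction columns where flagged. Column-to-term
#' bookkeeping is kept in attributes so the stepwise machinery can identify
#' each term's droppable top-order column.
#'
#' @param design a `wk_design`.
#' @param data data.frame of covariates (and `year` when interactions used).
#' @return numeric matrix with an `"(Intercept)"` column; attributes
#'   `term_of` (term index per column, 0 = intercept/year main effect) and
#'   `interaction` (logical per column).
#' @export
build_model_matrix <- function(design, data) {
  cols <- list(`(Intercept)` = matrix(1, nrow(data), 1,
                                      dimnames = list(NULL, "(Intercept)")))
  term_of <- 0L
  interaction <- FALSE
  any_by_year <- any(vapply(design$terms, function(t) t$by_year, TRUE))
  if (any_by_year) {
    if (!"year" %in% names(data)) stop_wk("year column required for year interactions")
    yr <- factor(data$year)
    if (nlevels(yr) < 2) stop_wk("year interactions need >= 2 year levels")
    Y <- stats::model.matrix(~yr)[, -1, drop = FALSE]
    colnames(Y) <- paste0("year", levels(yr)[-1])
    cols$year <- Y
    term_of <- c(term_of, rep(0L, ncol(Y)))
    interaction <- c(interaction, rep(FALSE, ncol(Y)))
  }
  for (i in seq_along(design$terms)) {
    tm <- design$terms[[i]]
    m <- term_columns(tm, data)
    cols[[length(cols) + 1L]] <- m
    term_of <- c(term_of, rep(i, ncol(m)))
    interaction <- c(interaction, rep(FALSE, ncol(m)))
    if (tm$by_year) {
      yr <- factor(data$year)
      Y <- stats::model.matrix(~yr)[, -1, drop = FALSE]
      for (k in seq_len(ncol(m))) {
        Int <- m[, k] * Y
        colnames(Int) <- paste0(colnames(m)[k], ":year", levels(yr)[-1])
        cols[[length(cols) + 1L]] <- Int
        term_of <- c(term_of, rep(i, ncol(Int)))
        interaction <- c(interaction, rep(TRUE, ncol(Int)))
      }
    }
  }
  X <- do.call(cbind, cols)
  structure(X, term_of = term_of, interaction = interaction)
}

# log-offset vector for a design (0 when no offset).
design_offset <- function(design, data) {
  if (is.null(design$offset)) return(rep(0, nrow(data)))
  if (!design$offset %in% names(data)) {
    stop_wk("offset column '", design$offset, "' not found in data")
  }
  v <- data[[design$offset]]
  if (any(v <= 0)) stop_wk("offset column must be positive to take logs")
  log(v)
}

# Replace a term's transform one step down the ladder; NULL = remove term.
step_down_term <- function(tm) {
  ord <- poly_order(tm$transform)
  if (is.na(ord) || ord == 1L) return(NULL)
  tm$transform <- c("linear", "quadratic", "cubic")[ord - 1L]
  tm
}

# Design with term i stepped down (or removed).
drop_top_order <- function(design, i) {
  tm <- step_down_term(design$terms[[i]])
  if (is.null(tm)) {
    design$terms[[i]] <- NULL
  } else {
    design$terms[[i]] <- tm
  }
  design
}

design_formula_text <- function(design) {
  lab <- vapply(design$terms, function(tm) {
    l <- term_label(tm)
    f <- switch(tm$transform,
                linear = l, quadratic = paste0("poly2(", l, ")"),
                cubic = paste0("poly3(", l, ")"), quartic = paste0("poly4(", l, ")"),
                log = paste0("log1p(", l, ")"), invlog = paste0("invlog(", l, ")"))
    if (tm$by_year) paste0(f, "*year") else f
  }, "")
  paste(design$response, "~", paste(lab, collapse = " + "))
}

#' @export
print.wk_design <- function(x, ...) {
  cat("<wk_design>", x$family, "\n ", design_formula_text(x), "\n")
  if (!is.null(x$offset)) cat("  offset: log(", x$offset, ")\n", sep = "")
  invisible(x)
}
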