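# Diagnostic battery: Vuong non-nested comparison, VIF, Moran's I on
# residuals, Nagelkerke pseudo-R^2, and repeated k-fold cross-validation.

#' Vuong test between two fits on the same observations
#'
#' Non-nested likelihood comparison used to decide whether a zero-inflated
#' model improves on its plain NB counterpart: with per-observation
#' log-likelihood differences `m_i = log f_a(y_i) - log f_b(y_i)`, the
#' statistic is `z = sqrt(n) * mean(m) / sd(m)` with a two-sided normal p.
#' The zero-inflated variant is adopted only on statistical improvement at
#' p < 0.05; otherwise `preferred = "neither"`. A degenerate comparison
#' (sd(m) ~ 0, e.g. a model against itself or an inflation component on the
#' boundary) gives z = 0, p = 1.
#'
#' @param fit_a,fit_b `wk_fit`/`wk_hurdle` objects fitted to identical
#'   observation vectors.
#' @param alpha decision level (default 0.05).
#' @return list: `statistic`, `p_value`, `preferred` (`"a"`, `"b"` or
#'   `"neither"`).
#' @export
vuong_test <- function(fit_a, fit_b, alpha = 0.05) {
  la <- obs_loglik(fit_a)
  lb <- obs_loglik(fit_b)
  if (length(la) != length(lb)) stop_wk("fits are not on the same observations")
  ya <- if (inherits(fit_a, "wk_hurdle")) fit_a$y else fit_a$y
  yb <- if (inherits(fit_b, "wk_hurdle")) fit_b$y else fit_b$y
  if (!isTRUE(all.equal(as.numeric(ya), as.numeric(yb)))) {
    stop_wk("fits are not on the same response values")
  }
  m <- la - lb
  n <- length(m)
  s <- stats::sd(m)
  if (!is.finite(s) || s < 1e-10) {
    return(list(statistic = 0, p_value = 1, preferred = "neither"))
  }
  z <- sqrt(n) * mean(m) / s
  p <- 2 * stats::pnorm(-abs(z))
  preferred <- if (p >= alpha) "neither" else if (z > 0) "a" else "b"
  list(statistic = z, p_value = p, preferred = preferred)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing column j on the remaining
#' columns (intercept included). Perfect collinearity is reported as `Inf`.
#' Pass/fail flags use the conventional thresholds applied in the modelling
#' protocol: 10 for all terms and 3 for non-interaction terms.
#'
#' @param X numeric model matrix (an intercept column is ignored).
#' @param interaction optional logical per column marking interaction terms
#'   (defaults to the `interaction` attribute of [build_model_matrix()]
#'   output, else all `FALSE`).
#' @return data.frame: `term`, `vif`, `interaction`, `pass`.
#' @export
vif <- function(X, interaction = NULL) {
  X <- as.matrix(X)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  if (is.null(interaction)) {
    interaction <- attr(X, "interaction") %||% rep(FALSE, ncol(X))
  }
  interaction <- interaction[keep]
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) stop_wk("need >= 2 non-constant columns")
  v <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  data.frame(term = colnames(X), vif = v, interaction = interaction,
             pass = v < ifelse(interaction, 10, 3), row.names = NULL)
}

#' Moran's I for spatial autocorrelation of residuals
#'
#' Global Moran's I with inverse-distance or fixed-band binary weights
#' (diagonal zero), expectation `-1/(n-1)`, and the normality-based z and
#' two-sided p.
#'
#' @param residuals numeric vector.
#' @param locations two-column (x, y) matrix/data.frame in km.
#' @param scheme `"idw"` (inverse distance, default) or `"band"`.
#' @param band neighbourhood radius in km for `"band"`.
#' @return list: `I`, `expected`, `sd`, `z`, `p`.
#' @export
morans_i <- function(residuals, locations, scheme = c("idw", "band"), band = 3) {
  scheme <- match.arg(scheme)
  n <- length(residuals)
  if (n < 10) stop_wk("need >= 10 locations")
  if (stats::sd(residuals) == 0) {
    return(list(I = NA_real_, expected = -1 / (n - 1), sd = NA_real_,
                z = NA_real_, p = NA_real_,
                note = "constant residuals: I undefined"))
  }
  D <- cross_dist(locations, locations)
  W <- if (scheme == "idw") 1 / pmax(D, 1e-6) else (D <= band) * 1
  diag(W) <- 0
  e <- residuals - mean(residuals)
  S0 <- sum(W)
  I <- n / S0 * drop(crossprod(e, W %*% e)) / sum(e^2)
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  z <- (I - EI) / sqrt(varI)
  list(I = I, expected = EI, sd = sqrt(varI), z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Nagelkerke pseudo-R^2
#'
#' `R^2 = (1 - exp(2 (l0 - l1) / n)) / (1 - exp(2 l0 / n))` from the fitted
#' and null log-likelihoods. A fitted log-likelihood below the null one (an
#' optimiser-failure signal) yields a negative value with a warning.
#'
#' @param fit,null_fit `wk_fit`/`wk_hurdle` objects on the same data, or
#'   raw log-likelihood numbers via `ll`/`ll0`/`n`.
#' @param ll,ll0,n optional raw inputs overriding the fit objects.
#' @return numeric in \[0, 1\] (negative only on optimiser failure).
#' @export
nagelkerke_r2 <- function(fit = NULL, null_fit = NULL, ll = NULL, ll0 = NULL,
                          n = NULL) {
  if (is.null(ll)) { ll <- fit$logLik; n <- fit$n }
  if (is.null(ll0)) ll0 <- null_fit$logLik
  num <- 1 - exp(2 * (ll0 - ll) / n)
  if (num < 0) warn_wk("fitted log-likelihood below null fit: check convergence")
  num / (1 - exp(2 * ll0 / n))
}

#' Repeated k-fold cross-validation
#'
#' Randomly partitions the data into k folds, fits on k-1 folds, predicts
#' the held-out fold on the response scale, and aggregates RMSE/MAE over
#' all held-out predictions; the partition is redrawn each run (fold seeds
#' are `seed + run`). Training metrics come from the full-data fit. For
#' hurdle designs a fold whose training part loses all positives (or all
#' zeros) is skipped with a warning and recorded.
#'
#' @param design a `wk_design`, or `list(zero = , count = )` for a hurdle.
#' @param data data.frame.
#' @param k folds (default 10) -- `n >= k` required.
#' @param runs repetitions (default 20).
#' @param seed base seed.
#' @return list of class `wk_cv`: `k`, `runs`, `rmse_training`,
#'   `mae_training`, `rmse_test`, `mae_test` (means over runs), `per_run`
#'   data.frame, `skipped_folds`.
#' @export
kfold_cv <- function(design, data, k = 10, runs = 20, seed = 1) {
  n <- nrow(data)
  if (k < 2) stop_wk("k must be >= 2")
  if (n < k) stop_wk("need n >= k")
  hurdle <- !inherits(design, "wk_design")
  fit_fun <- function(d) {
    if (hurdle) fit_hurdle(design$zero, design$count, d)
    else fit_design(design, d)
  }
  resp <- if (hurdle) design$count$response else design$response
  full <- fit_fun(data)
  pred_full <- predict_response(full, data)
  y <- data[[resp]]
  if (!hurdle && design$family == "logistic") y <- as.integer(y > 0)
  rmse <- function(e) sqrt(mean(e^2))
  mae <- function(e) mean(abs(e))
  err_tr <- y - pred_full
  per_run <- data.frame(run = seq_len(runs), rmse_test = NA_real_,
                        mae_test = NA_real_)
  skipped <- 0L
  for (r in seq_len(runs)) {
    set.seed(as.integer(seed) + r)
    fold <- sample(rep_len(seq_len(k), n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      train <- data[fold != f, , drop = FALSE]
      ft <- tryCatch(fit_fun(train), error = function(e) NULL)
      if (!is.null(ft) && inherits(ft, "wk_hurdle") &&
          !(inherits(ft$zero, "wk_fit") && inherits(ft$count, "wk_fit"))) {
        ft <- NULL
      }
      if (is.null(ft)) {
        skipped <- skipped + 1L
        warn_wk("run ", r, " fold ", f, " skipped (degenerate training part)")
        next
      }
      pred[fold == f] <- predict_response(ft, data[fold == f, , drop = FALSE])
    }
    ok <- !is.na(pred)
    per_run$rmse_test[r] <- rmse((y - pred)[ok])
    per_run$mae_test[r] <- mae((y - pred)[ok])
  }
  structure(list(k = k, runs = runs,
                 rmse_training = rmse(err_tr), mae_training = mae(err_tr),
                 rmse_test = mean(per_run$rmse_test),
                 mae_test = mean(per_run$mae_test),
                 per_run = per_run, skipped_folds = skipped),
            class = "wk_cv")
}

#' @export
print.wk_cv <- function(x, ...) {
  cat("<wk_cv> k =", x$k, "runs =", x$runs, "\n")
  cat(sprintf("  RMSE training %.4g / test %.4g\n", x$rmse_training, x$rmse_test))
  cat(sprintf("  MAE  training %.4g / test %.4g\n", x$mae_training, x$mae_test))
  if (x$skipped_folds) cat("  skipped folds:", x$skipped_folds, "\n")
  invisible(x)
}
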