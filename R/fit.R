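# Model-fitting core. NB parameterisation throughout is NB2:
# Var(y) = mu + mu^2 / theta.

new_wk_fit <- function(family, design, est, se, theta = NULL, ll, k, n,
                       fitted, y, X, off, deviance = NA_real_,
                       null_deviance = NA_real_, converged = TRUE,
                       boundary = FALSE) {
  z <- est / se
  structure(list(
    family = family, design = design,
    coefficients = est, se = se, z = z,
    p_values = 2 * stats::pnorm(-abs(z)),
    theta = theta, logLik = ll, df = k, n = n,
    aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
    deviance = deviance, null_deviance = null_deviance,
    fitted = fitted, y = y, X = X, offset = off,
    converged = converged, boundary = boundary), class = "wk_fit")
}

#' @export
print.wk_fit <- function(x, ...) {
  cat("<wk_fit>", x$family, " n =", x$n, "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se, p = x$p_values)
  print(round(tab, 4))
  if (!is.null(x$theta)) cat("theta:", signif(x$theta, 4), "\n")
  cat("logLik:", round(x$logLik, 2), " AIC:", round(x$aic, 2),
      " BIC:", round(x$bic, 2), "\n")
  if (!x$converged) cat("** fit did not converge **\n")
  invisible(x)
}

#' Fit a design to data
#'
#' Dispatches on the design's family: `"logistic"` (binomial GLM, logit
#' link), `"negbin"` (NB2 GLM, log link), `"ztnb"` (zero-truncated NB2 on
#' the positive observations), `"zinb"` (see [fit_zinb()]). Offsets enter
#' with coefficient fixed at 1 on the log scale.
#'
#' @param design a [design_spec()].
#' @param data data.frame of observations.
#' @return A `wk_fit`.
#' @export
fit_design <- function(design, data) {
  switch(design$family,
         logistic = fit_logistic(design, data),
         negbin = fit_negbin(design, data),
         ztnb = fit_ztnb(design, data),
         zinb = stop_wk("use fit_zinb() for zero-inflated fits"))
}

fit_logistic <- function(design, data) {
  X <- build_model_matrix(design, data)
  off <- design_offset(design, data)
  y <- data[[design$response]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) y <- as.integer(y > 0)
  if (all(y == 0) || all(y == 1)) {
    stop_wk("logistic response is all-", y[1], "; no finite MLE")
  }
  f <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                       offset = off))
  p <- ncol(X)
  R <- qr.R(f$qr)[seq_len(p), seq_len(p), drop = FALSE]
  vc <- chol2inv(R)
  se <- sqrt(diag(vc))
  ll <- sum(stats::dbinom(y, 1, f$fitted.values, log = TRUE))
  new_wk_fit("logistic", design, stats::setNames(f$coefficients, colnames(X)),
             stats::setNames(se, colnames(X)), theta = NULL, ll = ll, k = p,
             n = length(y), fitted = f$fitted.values, y = y, X = X, off = off,
             deviance = f$deviance, null_deviance = f$null.deviance,
             converged = f$converged)
}

#' Fit a negative binomial (NB2) GLM
#'
#' Log-link NB2 regression with an effort offset, the family used for whale
#' encounter counts. Estimation is by [MASS::glm.nb]; AIC/BIC count all
#' estimated parameters including the dispersion theta.
#'
#' @inheritParams fit_design
#' @return `wk_fit` with `theta` (> 0).
#' @export
fit_negbin <- function(design, data) {
  X <- build_model_matrix(design, data)
  off <- design_offset(design, data)
  y <- data[[design$response]]
  if (any(y < 0) || any(y != round(y))) {
    stop_wk("negbin response must be non-negative integers")
  }
  if (all(y == 0)) stop_wk("response is all zeros; no finite MLE for the intercept")
  p <- ncol(X)
  if (p > 1) {
    d <- as.data.frame(X[, -1, drop = FALSE])
    names(d) <- paste0("b", seq_len(p - 1))
  } else {
    d <- data.frame(row.names = seq_along(y))
  }
  d$.y <- y
  d$.off <- off
  rhs <- if (p > 1) paste(names(d)[seq_len(p - 1)], collapse = " + ") else "1"
  fml <- stats::as.formula(paste(".y ~", rhs, "+ offset(.off)"))
  f <- tryCatch(
    suppressWarnings(MASS::glm.nb(fml, data = d,
                                  control = stats::glm.control(maxit = 100))),
    error = function(e) NULL)
  boundary <- FALSE
  if (is.null(f) || !is.finite(f$theta)) {
    # equidispersed data: theta diverges; report the Poisson-limit fit with
    # theta at a large boundary value
    f <- suppressWarnings(stats::glm(fml, data = d, family = stats::poisson()))
    f$theta <- 1e5
    boundary <- TRUE
  }
  est <- stats::setNames(stats::coef(f), colnames(X))
  se <- stats::setNames(sqrt(diag(stats::vcov(f))), colnames(X))
  mu <- f$fitted.values
  ll <- sum(stats::dnbinom(y, size = f$theta, mu = mu, log = TRUE))
  new_wk_fit("negbin", design, est, se, theta = f$theta, ll = ll, k = p + 1,
             n = length(y), fitted = mu, y = y, X = X, off = off,
             deviance = f$deviance, null_deviance = f$null.deviance,
             converged = f$converged %||% TRUE, boundary = boundary)
}

# Zero-truncated NB2 log-likelihood and analytic gradient.
ztnb_negll <- function(par, X, y, off) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + off
  mu <- exp(eta)
  theta <- exp(par[p + 1])
  lp0 <- theta * (log(theta) - log(theta + mu))
  ll <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE) -
    log1p(-exp(lp0))
  -sum(ll)
}

ztnb_negll_grad <- function(par, X, y, off) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)]) + off
  mu <- exp(eta)
  theta <- exp(par[p + 1])
  p0 <- exp(theta * (log(theta) - log(theta + mu)))
  om <- 1 - p0
  deta <- y - (y + theta) * mu / (theta + mu) -
    p0 * theta * mu / (om * (theta + mu))
  dtheta <- digamma(y + theta) - digamma(theta) +
    log(theta / (theta + mu)) + 1 - (y + theta) / (theta + mu) +
    p0 * (log(theta / (theta + mu)) + mu / (theta + mu)) / om
  -c(drop(crossprod(X, deta)), sum(dtheta) * theta)
}

#' Fit a zero-truncated NB2 model to the positive observations
#'
#' The count part of the hurdle model: `P(y | y > 0) =
#' NB(y; mu, theta) / (1 - NB(0; mu, theta))` with `mu = exp(X beta +
#' offset)`. Maximised by BFGS with analytic gradients from a Poisson
#' start; standard errors from the numerically differentiated Hessian.
#'
#' @inheritParams fit_design
#' @return `wk_fit` on the `y > 0` subset.
#' @export
fit_ztnb <- function(design, data) {
  y_all <- data[[design$response]]
  pos <- which(y_all > 0)
  if (!length(pos)) stop_wk("no positive observations for the truncated part")
  data <- data[pos, , drop = FALSE]
  X <- build_model_matrix(design, data)
  off <- design_offset(design, data)
  y <- y_all[pos]
  if (any(y != round(y))) stop_wk("ztnb response must be integer")
  p <- ncol(X)
  start_fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                               offset = off))
  mu0 <- start_fit$fitted.values
  v <- stats::var(y)
  th0 <- max(mean(y)^2 / max(v - mean(y), mean(y) / 10), 0.05)
  par0 <- c(start_fit$coefficients, log(th0))
  opt <- stats::optim(par0, ztnb_negll, ztnb_negll_grad, X = X, y = y,
                      off = off, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  H <- stats::optimHess(opt$par, ztnb_negll, ztnb_negll_grad, X = X, y = y,
                        off = off)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA, p + 1, p + 1))
  se <- sqrt(pmax(diag(vc)[seq_len(p)], 0))
  theta <- exp(opt$par[p + 1])
  mu <- exp(drop(X %*% opt$par[seq_len(p)]) + off)
  p0 <- stats::dnbinom(0, size = theta, mu = mu)
  new_wk_fit("ztnb", design,
             stats::setNames(opt$par[seq_len(p)], colnames(X)),
             stats::setNames(se, colnames(X)),
             theta = theta, ll = -opt$value, k = p + 1, n = length(y),
             fitted = mu / (1 - p0), y = y, X = X, off = off,
             converged = opt$convergence == 0)
}

#' Fit a two-part hurdle model
#'
#' The krill abundance model: a logistic part for zero versus positive and
#' a zero-truncated NB2 part conditional on positivity. The two likelihoods
#' are orthogonal, so the parts are estimated independently; combined
#' AIC/BIC sum the parts with the total parameter count. The effort offset
#' (log acoustic volume) enters the count part only by default.
#'
#' @param zero_design logistic-family design for presence/absence; its
#'   response is the positivity indicator of the count response.
#' @param count_design ztnb-family design for the positive counts.
#' @param data data.frame of observations.
#' @return list of class `wk_hurdle` with elements `zero`, `count`
#'   (each a `wk_fit` or a condition if that part was degenerate), `aic`,
#'   `bic`, `logLik`, `df`, `n`.
#' @export
fit_hurdle <- function(zero_design, count_design, data) {
  if (zero_design$family != "logistic") stop_wk("zero part must be logistic")
  if (count_design$family != "ztnb") stop_wk("count part must be ztnb")
  y <- data[[count_design$response]]
  zd <- zero_design
  fits <- list(
    zero = tryCatch(fit_logistic(zd, data), error = function(e) e),
    count = tryCatch(fit_ztnb(count_design, data), error = function(e) e))
  ok <- vapply(fits, inherits, TRUE, "wk_fit")
  if (!any(ok)) stop_wk("both hurdle parts failed: ",
                        conditionMessage(fits$zero))
  ll <- sum(vapply(fits[ok], function(f) f$logLik, 0))
  k <- sum(vapply(fits[ok], function(f) f$df, 0))
  n <- if (ok[["zero"]]) fits$zero$n else fits$count$n
  structure(list(zero = fits$zero, count = fits$count,
                 logLik = ll, df = k, n = n,
                 aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
                 y = y), class = "wk_hurdle")
}

#' @export
print.wk_hurdle <- function(x, ...) {
  cat("<wk_hurdle> combined AIC:", round(x$aic, 2), " BIC:", round(x$bic, 2), "\n")
  cat("-- zero part --\n"); print(x$zero)
  cat("-- count part --\n"); print(x$count)
  invisible(x)
}

# ZINB log-likelihood (pi from logistic zero part, NB2 count part).
zinb_negll <- function(par, X, Z, y, off) {
  p <- ncol(X); q <- ncol(Z)
  mu <- exp(drop(X %*% par[seq_len(p)]) + off)
  pi <- stats::plogis(drop(Z %*% par[p + seq_len(q)]))
  theta <- exp(par[p + q + 1])
  lnb <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  ll <- numeric(length(y))
  z0 <- y == 0
  ll[z0] <- log(pi[z0] + (1 - pi[z0]) * exp(lnb[z0]))
  ll[!z0] <- log1p(-pi[!z0]) + lnb[!z0]
  -sum(ll)
}

#' Fit a zero-inflated negative binomial model
#'
#' Mixture of a point mass at zero (inflation probability from a logistic
#' linear predictor, which may include detection-condition covariates) and
#' an NB2 count component with offset. Joint maximum likelihood by BFGS
#' from an NB start. An inflation probability collapsing to zero is
#' reported as a boundary fit, not a failure.
#'
#' @param count_design negbin-family design for the count component.
#' @param zero_design logistic-family design for the inflation component
#'   (response ignored; linear predictor only).
#' @param data data.frame.
#' @return `wk_fit` with family `"zinb"`; coefficients are the count-part
#'   coefficients followed by zero-part coefficients prefixed `zero_`.
#' @export
fit_zinb <- function(count_design, zero_design, data) {
  y <- data[[count_design$response]]
  if (all(y == 0)) stop_wk("response is all zeros")
  X <- build_model_matrix(count_design, data)
  Z <- build_model_matrix(zero_design, data)
  off <- design_offset(count_design, data)
  p <- ncol(X); q <- ncol(Z)
  nb0 <- fit_negbin(count_design, data)
  par0 <- c(nb0$coefficients, c(-2, rep(0, q - 1)), log(nb0$theta))
  opt <- stats::optim(par0, zinb_negll, X = X, Z = Z, y = y, off = off,
                      method = "BFGS", control = list(maxit = 1000))
  H <- stats::optimHess(opt$par, zinb_negll, X = X, Z = Z, y = y, off = off)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA, p + q + 1, p + q + 1))
  se <- sqrt(pmax(diag(vc)[seq_len(p + q)], 0))
  nm <- c(colnames(X), paste0("zero_", colnames(Z)))
  theta <- exp(opt$par[p + q + 1])
  mu <- exp(drop(X %*% opt$par[seq_len(p)]) + off)
  pi <- stats::plogis(drop(Z %*% opt$par[p + seq_len(q)]))
  fit <- new_wk_fit("zinb", count_design,
                    stats::setNames(opt$par[seq_len(p + q)], nm),
                    stats::setNames(se, nm), theta = theta, ll = -opt$value,
                    k = p + q + 1, n = length(y),
                    fitted = (1 - pi) * mu, y = y, X = X, off = off,
                    converged = opt$convergence == 0,
                    boundary = max(pi) < 1e-4)
  fit$zero_design <- zero_design
  fit$pi <- pi
  fit
}

# Hurdle expected value E[y] = pi * mu / (1 - NB(0; mu, theta)).
hurdle_mean <- function(pi, mu, theta) {
  p0 <- stats::dnbinom(0, size = theta, mu = mu)
  pi * mu / (1 - p0)
}

#' Predict on the response scale
#'
#' @param fit a `wk_fit` or `wk_hurdle`.
#' @param newdata data.frame of covariates.
#' @param effort effort on the raw scale: `NULL` uses the design's offset
#'   column from `newdata`; a scalar or vector is used directly (1 gives
#'   per-unit-effort predictions, the convention for mapped abundance).
#' @return numeric vector: presence probability (logistic), expected count
#'   (negbin/zinb), truncated mean (ztnb), or combined hurdle mean
#'   `P(presence) * mu / (1 - NB(0))`.
#' @export
predict_response <- function(fit, newdata, effort = NULL) {
  if (inherits(fit, "wk_hurdle")) {
    pr <- predict_response(fit$zero, newdata, effort = 1)
    des <- fit$count$design
    X <- build_model_matrix(des, newdata)
    eta <- drop(X %*% fit$count$coefficients) + pred_offset(des, newdata, effort)
    return(hurdle_mean(pr, exp(eta), fit$count$theta))
  }
  des <- fit$design
  X <- build_model_matrix(des, newdata)
  p <- sum(!startsWith(names(fit$coefficients), "zero_"))
  eta <- drop(X %*% fit$coefficients[seq_len(p)]) +
    pred_offset(des, newdata, effort)
  switch(fit$family,
         logistic = stats::plogis(eta),
         negbin = exp(eta),
         ztnb = {
           mu <- exp(eta)
           mu / (1 - stats::dnbinom(0, size = fit$theta, mu = mu))
         },
         zinb = {
           Z <- build_model_matrix(fit$zero_design, newdata)
           q <- ncol(Z)
           pi <- stats::plogis(drop(Z %*% fit$coefficients[p + seq_len(q)]))
           (1 - pi) * exp(eta)
         })
}

pred_offset <- function(design, newdata, effort) {
  if (!is.null(effort)) {
    return(log(rep(effort, length.out = nrow(newdata))))
  }
  design_offset(design, newdata)
}

# Per-observation log-likelihood, the Vuong test's raw material.
obs_loglik <- function(fit) {
  if (inherits(fit, "wk_hurdle")) {
    y <- fit$y
    pz <- fit$zero$fitted
    ll <- numeric(length(y))
    ll[y == 0] <- log(1 - pz[y == 0])
    mu <- exp(drop(fit$count$X %*% fit$count$coefficients) + fit$count$offset)
    p0 <- stats::dnbinom(0, size = fit$count$theta, mu = mu)
    ll[y > 0] <- log(pz[y > 0]) +
      stats::dnbinom(fit$count$y, size = fit$count$theta, mu = mu, log = TRUE) -
      log1p(-p0)
    return(ll)
  }
  y <- fit$y
  switch(fit$family,
         logistic = stats::dbinom(y, 1, fit$fitted, log = TRUE),
         negbin = stats::dnbinom(y, size = fit$theta, mu = fit$fitted, log = TRUE),
         ztnb = {
           mu <- exp(drop(fit$X %*% fit$coefficients) + fit$offset)
           stats::dnbinom(y, size = fit$theta, mu = mu, log = TRUE) -
             log1p(-stats::dnbinom(0, size = fit$theta, mu = mu))
         },
         zinb = {
           p <- ncol(fit$X)
           mu <- exp(drop(fit$X %*% fit$coefficients[seq_len(p)]) + fit$offset)
           pi <- fit$pi
           lnb <- stats::dnbinom(y, size = fit$theta, mu = mu, log = TRUE)
           ifelse(y == 0, log(pi + (1 - pi) * exp(lnb)), log1p(-pi) + lnb)
         })
}
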