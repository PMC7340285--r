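# Fitting families, information criteria and the diagnostic battery.

test_that("NB2 fit recovers simulated parameters and handles limits", {
  set.seed(1)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  d$y <- rnbinom(n, size = 2, mu = exp(1 + 0.5 * d$x))
  des <- design_spec("y", list(term_spec("x")), family = "negbin")
  f <- fit_design(des, d)
  expect_true(all(abs(f$coefficients - c(1, 0.5)) < 3 * f$se))
  expect_lt(abs(f$theta - 2) / 2, 0.20)
  # Poisson data: theta escapes upward, coefficients match the Poisson fit
  set.seed(2)
  dp <- data.frame(x = rnorm(2000))
  dp$y <- rpois(2000, exp(0.5 + 0.3 * dp$x))
  fp <- suppressWarnings(fit_design(design_spec("y", list(term_spec("x")),
                                                family = "negbin"), dp))
  pois <- glm(y ~ x, poisson(), dp)
  expect_gt(fp$theta, 50)
  expect_lt(max(abs(fp$coefficients - coef(pois))), 1e-2)
  # degenerate input
  dz <- data.frame(x = rnorm(20), y = rep(0L, 20))
  expect_error(fit_design(design_spec("y", list(term_spec("x")),
                                      family = "negbin"), dz), "all zeros")
})

test_that("offsets enter NB fits with coefficient one", {
  set.seed(3)
  n <- 3000
  d <- data.frame(x = rnorm(n), eff = runif(n, 1, 20))
  d$y <- rnbinom(n, size = 2, mu = exp(-1 + 0.4 * d$x) * d$eff)
  f <- fit_design(design_spec("y", list(term_spec("x")), offset = "eff",
                              family = "negbin"), d)
  expect_true(all(abs(f$coefficients - c(-1, 0.4)) < 3 * f$se))
})

test_that("truncated NB pmf is properly normalised", {
  mu <- 3; theta <- 2
  p0 <- dnbinom(0, size = theta, mu = mu)
  total <- sum(dnbinom(1:500, size = theta, mu = mu)) / (1 - p0)
  expect_lt(abs(total - 1), 1e-8)
})

test_that("hurdle fit recovers all four slopes/intercepts and theta", {
  d <- sim_hurdle_data(5000, seed = 4)
  zd <- design_spec("y", list(term_spec("x")), family = "logistic")
  cd <- design_spec("y", list(term_spec("x")), family = "ztnb")
  h <- fit_hurdle(zd, cd, d)
  expect_true(all(abs(h$zero$coefficients - c(-0.5, 1.0)) < 3 * h$zero$se))
  expect_true(all(abs(h$count$coefficients - c(2, 0.8)) < 3 * h$count$se))
  expect_lt(abs(h$count$theta - 1.5) / 1.5, 0.25)
  # combined information criteria sum the parts
  expect_equal(h$aic, h$zero$aic + h$count$aic)
  expect_equal(h$df, h$zero$df + h$count$df)
  # the degenerate part errors, the other still fits
  dall <- d; dall$y <- pmax(dall$y, 1L) # no zeros
  h2 <- suppressWarnings(fit_hurdle(zd, cd, dall))
  expect_s3_class(h2$count, "wk_fit")
  expect_false(inherits(h2$zero, "wk_fit"))
})

test_that("hurdle expected value matches Monte-Carlo at (0.6, 3, 2)", {
  set.seed(5)
  n <- 4e5
  pres <- rbinom(n, 1, 0.6)
  p0 <- dnbinom(0, size = 2, mu = 3)
  y <- ifelse(pres == 1,
              qnbinom(runif(n, p0, 1), size = 2, mu = 3), 0)
  expect_lt(abs(mean(y) - whalekrill:::hurdle_mean(0.6, 3, 2)) /
              whalekrill:::hurdle_mean(0.6, 3, 2), 0.01)
})

test_that("ZINB collapses to NB without excess zeros and recovers pi with them", {
  set.seed(6)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  d$y <- rnbinom(n, size = 2, mu = exp(1 + 0.5 * d$x))
  cd <- design_spec("y", list(term_spec("x")), family = "negbin")
  zz <- design_spec("y", list(), family = "logistic")
  zf <- fit_zinb(cd, zz, d)
  nb <- fit_design(cd, d)
  expect_lt(max(abs(zf$coefficients[1:2] - nb$coefficients)), 1e-2)
  expect_lt(mean(zf$pi), 0.02)
  # strong inflation recovered
  set.seed(7)
  d$y <- ifelse(rbinom(n, 1, 0.3) == 1, 0L,
                rnbinom(n, size = 2, mu = exp(1 + 0.5 * d$x)))
  zf2 <- fit_zinb(cd, zz, d)
  expect_true(mean(zf2$pi) > 0.25 && mean(zf2$pi) < 0.35)
  # all-zero response errors
  dz <- data.frame(x = rnorm(30), y = 0L)
  expect_error(fit_zinb(cd, zz, dz), "zeros")
})

test_that("AIC and BIC agree with an independent likelihood evaluation", {
  # 5-observation hand case: evaluate the NB2 likelihood from first
  # principles at the fitted parameters and rebuild the criteria
  d <- data.frame(y = c(0L, 1L, 3L, 2L, 5L), x = c(-1, -0.5, 0, 0.5, 1))
  f <- suppressWarnings(fit_design(design_spec("y", list(term_spec("x")),
                                               family = "negbin"), d))
  ll <- nb2_loglik_manual(d$y, f$fitted, f$theta)
  k <- 3 # intercept, slope, theta
  expect_equal(f$logLik, ll, tolerance = 1e-6)
  expect_equal(f$aic, 2 * k - 2 * ll, tolerance = 1e-6)
  expect_equal(f$bic, k * log(5) - 2 * ll, tolerance = 1e-6)
})

test_that("Vuong test: self-comparison is degenerate, inflation is detected", {
  set.seed(8)
  d <- data.frame(x = rnorm(2000))
  d$y <- rnbinom(2000, size = 2, mu = exp(0.5 + 0.5 * d$x))
  cd <- design_spec("y", list(term_spec("x")), family = "negbin")
  f <- fit_design(cd, d)
  v <- vuong_test(f, f)
  expect_equal(v$statistic, 0)
  expect_equal(v$p_value, 1)
  expect_equal(v$preferred, "neither")
  # power: strongly inflated data prefer the zero-inflated model
  set.seed(9)
  d$y <- ifelse(rbinom(2000, 1, 0.5) == 1, 0L,
                rnbinom(2000, size = 2, mu = exp(1.5 + 0.5 * d$x)))
  zz <- design_spec("y", list(), family = "logistic")
  nb <- fit_design(cd, d)
  zi <- fit_zinb(cd, zz, d)
  v2 <- vuong_test(nb, zi)
  expect_equal(v2$preferred, "b")
  expect_lt(v2$p_value, 0.001)
  # mismatched observations are rejected
  f2 <- fit_design(cd, d[1:1000, ])
  expect_error(vuong_test(f, f2), "same observations")
})

test_that("VIF matches closed forms and flags collinearity", {
  # exactly orthogonal, centred columns -> all VIF 1
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  v <- vif(X)
  expect_equal(v$vif, rep(1, 3))
  # duplicated column -> infinite VIF, flagged
  Xd <- cbind(X, d = X[, 1])
  vd <- vif(Xd)
  expect_true(is.infinite(vd$vif[vd$term == "a"]))
  expect_false(all(vd$pass))
  # correlation 0.9 -> VIF = 1/(1-0.81) ~ 5.263, via an exact construction
  e1 <- c(1, 1, -1, -1) / 2; e2 <- c(1, -1, 1, -1) / 2
  x1 <- e1
  x2 <- 0.9 * e1 + sqrt(1 - 0.81) * e2
  v9 <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(v9$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
})

test_that("Moran's I signs anti- and positively correlated residual fields", {
  # checkerboard on a 6x6 grid with rook (band-1) weights -> negative I
  g <- expand.grid(x = 1:6, y = 1:6)
  chk <- (-1)^(g$x + g$y)
  mi <- morans_i(chk, g, scheme = "band", band = 1)
  expect_lt(mi$I, 0)
  expect_lt(mi$p, 0.01)
  # smooth residuals -> strong positive I
  gg <- make_study_grid(c(12, 10), 1)
  sm <- simulate_field(gg, sill = 1, range_km = 6, nugget = 0, seed = 10)
  mi2 <- morans_i(sm, gg[, c("x", "y")], scheme = "band", band = 2)
  expect_gt(mi2$I, 0)
  expect_lt(mi2$p, 0.01)
  # degenerate input reported, not crashed
  mc <- morans_i(rep(1, 20), cbind(runif(20), runif(20)))
  expect_true(is.na(mc$I))
  expect_equal(mi$expected, -1 / 35)
})

test_that("Nagelkerke R2 matches hand arithmetic and its bounds", {
  expect_equal(nagelkerke_r2(ll = -100, ll0 = -120, n = 100),
               (1 - exp(-0.4)) / (1 - exp(-2.4)), tolerance = 1e-12)
  expect_equal(nagelkerke_r2(ll = -120, ll0 = -120, n = 100), 0)
  expect_warning(r <- nagelkerke_r2(ll = -121, ll0 = -120, n = 100), "below null")
  expect_lt(r, 0)
})

test_that("k-fold CV is deterministic and near-exact on noiseless data", {
  d <- data.frame(y = 1:50, x = log(1:50))
  des <- design_spec("y", list(term_spec("x")), family = "negbin")
  cv1 <- suppressWarnings(kfold_cv(des, d, k = 5, runs = 3, seed = 1))
  cv2 <- suppressWarnings(kfold_cv(des, d, k = 5, runs = 3, seed = 1))
  expect_identical(cv1$per_run, cv2$per_run)
  expect_lt(cv1$rmse_test, 0.1)
  expect_lt(cv1$rmse_training, 0.1)
  expect_error(kfold_cv(des, d[1:3, ], k = 5), "n >= k")
})

test_that("test error exceeds training error on overfit-prone simulations", {
  gap <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 100
    d <- data.frame(matrix(rnorm(n * 8), n, 8))
    names(d) <- paste0("z", 1:8)
    d$y <- rnbinom(n, size = 2, mu = exp(0.5 + 0.3 * d$z1))
    des <- design_spec("y", lapply(paste0("z", 1:8), term_spec),
                       family = "negbin")
    cv <- suppressWarnings(kfold_cv(des, d, k = 5, runs = 2, seed = s))
    cv$rmse_test >= cv$rmse_training
  })
  expect_gt(mean(gap), 0.5)
})

test_that("fits are reproducible: same data and spec give identical reports", {
  d <- sim_hurdle_data(800, seed = 12)
  zd <- design_spec("y", list(term_spec("x")), family = "logistic")
  cd <- design_spec("y", list(term_spec("x")), family = "ztnb")
  h1 <- fit_hurdle(zd, cd, d)
  h2 <- fit_hurdle(zd, cd, d)
  expect_identical(h1$count$coefficients, h2$count$coefficients)
  expect_identical(h1$aic, h2$aic)
})
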