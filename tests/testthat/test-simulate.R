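# Synthetic-study generator: fields, climate, observations.

test_that("field simulation honours trend-only and determinism contracts", {
  g <- make_study_grid(c(10, 8), 1)
  f0 <- simulate_field(g, sill = 0, range_km = 5, nugget = 0,
                       trend_coeffs = c("1" = 7), seed = 1)
  expect_equal(f0, rep(7, nrow(g)))
  f1 <- simulate_field(g, sill = 1, range_km = 5, nugget = 0.1, seed = 42)
  f2 <- simulate_field(g, sill = 1, range_km = 5, nugget = 0.1, seed = 42)
  expect_identical(f1, f2)
  f3 <- simulate_field(g, sill = 1, range_km = 5, nugget = 0.1, seed = 43)
  expect_false(identical(f1, f3))
  expect_error(simulate_field(g, sill = 0.5, range_km = 5, nugget = 0.8, seed = 1),
               "sill >= nugget")
  expect_error(simulate_field(g, sill = 1, range_km = -1, seed = 1), "range")
})

test_that("empirical semivariance flattens at the sill beyond the range", {
  # exponential covariance: gamma(h) -> sill for h >> range
  g <- make_study_grid(c(50, 50), 1)
  f <- simulate_field(g, sill = 1, range_km = 5, nugget = 0, seed = 99)
  emp <- empirical_variogram(g[, c("x", "y")], f, n_lags = 12, max_lag = 35)
  far <- emp$gamma[emp$lag > 20] # > 4 ranges out
  expect_lt(abs(mean(far) - 1), 0.15)
})

test_that("climate series have the requested AR(1) structure", {
  expect_equal(simulate_climate(50, ar_coeff = 0.5, sd = 0, seed = 1, mean = 2),
               rep(2, 50))
  s0 <- simulate_climate(1e4, ar_coeff = 0, sd = 1, seed = 5)
  expect_lt(abs(acf(s0, plot = FALSE)$acf[2]), 0.03)
  s8 <- simulate_climate(1e4, ar_coeff = 0.8, sd = 1, seed = 6)
  expect_lt(abs(acf(s8, plot = FALSE)$acf[2] - 0.8), 0.05)
  expect_error(simulate_climate(10, ar_coeff = 1), "nonstationary")
  expect_error(simulate_climate(10, ar_coeff = -1.2), "nonstationary")
})

test_that("climate table covers all lags for every cruise month", {
  cl <- make_climate_table(2004:2005, seed = 3)
  cr <- make_cruises(2004:2005, c(5, 6, 7, 9), cl)
  expect_equal(nrow(cr), 8)
  lag_cols <- grep("_lag", names(cr), value = TRUE)
  expect_length(lag_cols, 16) # 4 indices x 4 lags
  expect_false(anyNA(cr[, lag_cols]))
  # lag-0 May value equals the May entry of the monthly table
  i <- which(cr$year == 2004 & cr$month == 5)
  expect_equal(cr$soi_lag0[i], cl$soi[cl$year == 2004 & cl$month == 5])
  expect_equal(cr$soi_lag3[i], cl$soi[cl$year == 2004 & cl$month == 2])
  expect_error(make_cruises(2004, months = c(4, 5), cl), "restricted")
})

make_test_setup <- function(years = 2004, months = c(5, 6)) {
  grid <- make_study_grid(c(20, 12), 1)
  truth <- default_truth_spec(1)
  cl <- make_climate_table(years, seed = 2)
  cruises <- make_cruises(years, months, cl)
  list(grid = grid, truth = truth, cruises = cruises)
}

test_that("observations are reproducible and obey the discard rule", {
  s <- make_test_setup()
  b1 <- simulate_observations(s$grid, s$cruises, s$truth, seed = 7)
  b2 <- simulate_observations(s$grid, s$cruises, s$truth, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$length >= 1))
  expect_true(all(b1$krill_biomass >= 0))
  expect_true(all(b1$blue_count >= 0))
  expect_true(all(b1$g0 > 0 & b1$g0 <= 1))
  expect_true(all(b1$esw > 0))
  # end-of-line discard exercised: transect length 19 km -> 3-km bins leave
  # a 1-km tail which is kept, but a 0.5-km tail must vanish
  b3 <- simulate_observations(s$grid, s$cruises, s$truth, seed = 7,
                              transect_length_km = 18.5)
  expect_true(all(b3$length >= 1))
  expect_lt(max(tapply(b3$length, b3$cruise_id, sum)), 18.5 * 3 + 1e-9)
})

test_that("a truth covariate missing from bins is reported by name", {
  s <- make_test_setup()
  tr <- s$truth
  tr$blue$terms[[1]]$covariate <- "no_such_covariate"
  expect_error(simulate_observations(s$grid, s$cruises, tr, seed = 1),
               "no_such_covariate")
})

test_that("saturated presence intercept produces all zeros", {
  s <- make_test_setup()
  tr <- s$truth
  tr$krill_presence$beta[1] <- tr$krill_presence$beta[1] - 40 # logit -> -inf
  b <- simulate_observations(s$grid, s$cruises, tr, seed = 3)
  expect_true(all(b$krill_biomass == 0))
})

test_that("count means follow the truth: LLN, offset scaling, NB variance", {
  # intercept-only NB with unit offset: sample mean -> exp(log 2) = 2
  n <- 1e4
  set.seed(11)
  y <- rnbinom(n, size = 2, mu = 2)
  expect_lt(abs(mean(y) - 2) / 2, 0.05)
  # NB variance fidelity: var = mu + mu^2/theta within 10%
  expect_lt(abs(var(y) - (2 + 4 / 2)) / (2 + 4 / 2), 0.10)
  # doubling survey area doubles the expected whale count (offset contract)
  s <- make_test_setup()
  b <- simulate_observations(s$grid, s$cruises, s$truth, seed = 5)
  e1 <- truth_expected(s$truth$blue, b, offset = b$survey_area)
  e2 <- truth_expected(s$truth$blue, b, offset = 2 * b$survey_area)
  expect_equal(e2, 2 * e1)
})

test_that("zero fraction matches the Bernoulli part of the hurdle truth", {
  grid <- make_study_grid(c(30, 20), 1)
  truth <- default_truth_spec(1)
  cl <- make_climate_table(2004:2011, seed = 2)
  cruises <- make_cruises(2004:2011, c(5, 6, 7, 9), cl)
  b <- simulate_observations(grid, cruises, truth, seed = 9,
                             transect_spacing_km = 3)
  expect_gt(nrow(b), 1500)
  p_pres <- truth_expected(truth$krill_presence, b, type = "prob")
  observed_zero <- mean(b$krill_biomass == 0)
  expect_lt(abs(observed_zero - (1 - mean(p_pres))), 0.02)
})

test_that("truth specs round-trip through JSON", {
  tr <- default_truth_spec(4)
  path <- tempfile(fileext = ".json")
  write_truth_spec(tr, path)
  tr2 <- read_truth_spec(path)
  expect_equal(tr2$blue$beta, tr$blue$beta)
  expect_equal(tr2$krill_count$theta, tr$krill_count$theta)
  expect_equal(tr2$fields$temp_surf$sill, tr$fields$temp_surf$sill)
  expect_equal(tr2$blue$terms[[1]]$transform, "quadratic")
  unlink(path)
})
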