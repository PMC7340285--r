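# Segment densities, grid prediction, temporal averaging, decile scaling.

test_that("segment density follows the line-transect formula", {
  expect_equal(segment_density(0, 3, 1.2, 0.9), 0)
  expect_equal(segment_density(2, 3, 1, 1), 1 / 3)
  # halving g(0) doubles the density
  expect_equal(segment_density(4, 3, 1.2, 0.4),
               2 * segment_density(4, 3, 1.2, 0.8))
  expect_error(segment_density(1, 0, 1, 1), "length")
  expect_error(segment_density(1, 3, 0, 1), "esw")
  expect_error(segment_density(1, 3, 1, 0), "g0")
  expect_error(segment_density(1, 3, 1, 1.2), "g0")
})

test_that("grid prediction matches the generator's expected surface", {
  grid <- make_study_grid(c(20, 12), 1)
  truth <- default_truth_spec(1)
  cl <- make_climate_table(2004, seed = 2)
  cruises <- make_cruises(2004, c(5, 6), cl)
  bins <- simulate_observations(grid, cruises, truth, seed = 3)
  # a wk_fit whose coefficients ARE the truth predicts the truth surface
  des <- design_spec("blue_count", truth$blue$terms, offset = "survey_area",
                     family = "negbin")
  f <- fit_design(des, bins)
  f$coefficients[] <- truth$blue$beta
  gdat <- grid
  fseed <- whalekrill:::derive_seeds(11, length(truth$fields))
  for (k in seq_along(truth$fields)) {
    fp <- truth$fields[[k]]
    gdat[[names(truth$fields)[k]]] <- simulate_field(
      grid, fp$sill, fp$range_km, fp$nugget, fp$trend_coeffs, seed = fseed[k])
  }
  for (cl2 in grep("_lag", names(cruises), value = TRUE)) {
    gdat[[cl2]] <- cruises[[cl2]][1]
  }
  pred <- predict_grid(f, gdat, "blue", 2004, 5)
  manual <- truth_expected(truth$blue, gdat) # unit effort
  expect_equal(pred$values, manual, tolerance = 1e-6)
  expect_true(all(pred$values >= 0))
})

test_that("intercept-only and presence-probability-one limits hold", {
  d <- data.frame(y = rpois(200, 3), x = rnorm(200))
  des <- design_spec("y", list(term_spec("x")), family = "negbin")
  f <- suppressWarnings(fit_design(des, d))
  f$coefficients[] <- c(1.5, 0) # constant linear predictor
  nd <- data.frame(x = rnorm(25))
  pred <- predict_response(f, nd, effort = 1)
  expect_equal(pred, rep(exp(1.5), 25))
  # hurdle with presence probability 1 reduces to the truncated-NB mean
  dh <- sim_hurdle_data(1500, seed = 5)
  zd <- design_spec("y", list(term_spec("x")), family = "logistic")
  cd <- design_spec("y", list(term_spec("x")), family = "ztnb")
  h <- fit_hurdle(zd, cd, dh)
  h$zero$coefficients[] <- c(40, 0) # plogis(40) == 1
  ph <- predict_response(h, nd, effort = 1)
  mu <- exp(h$count$coefficients[1] + h$count$coefficients[2] * nd$x)
  expect_equal(ph, mu / (1 - dnbinom(0, size = h$count$theta, mu = mu)),
               tolerance = 1e-12)
})

test_that("averaging schemes weight years, not months", {
  r <- function(v, y, m) prediction_raster(rep(v, 4), "krill", y, m)
  # year A contributes months {2, 4} (mean 3), year B contributes {9}:
  # two-stage overall mean is 6, not the pooled 5
  rl <- list(r(2, 2004, 5), r(4, 2004, 6), r(9, 2005, 5))
  ov <- average_maps(rl, "overall")
  expect_equal(ov$values, rep(6, 4))
  pooled <- Reduce(`+`, lapply(rl, function(x) x$values)) / 3
  expect_equal(pooled, rep(5, 4))
  # monthly: May over two years uses exactly the two May rasters
  mo <- average_maps(rl, "monthly")
  expect_equal(mo[["5"]]$values, rep((2 + 9) / 2, 4))
  expect_equal(nrow(attr(mo[["5"]], "provenance")), 2)
  # annual within-year means
  an <- average_maps(rl, "annual")
  expect_equal(an[["2004"]]$values, rep(3, 4))
  # identical rasters average to themselves
  same <- average_maps(list(r(7, 2004, 5), r(7, 2005, 5)), "overall")
  expect_equal(same$values, rep(7, 4))
  expect_error(average_maps(list(), "overall"), "empty")
})

test_that("two-stage equals pooled mean iff month counts are balanced", {
  r <- function(v, y, m) prediction_raster(v, "krill", y, m)
  set.seed(9)
  balanced <- list(r(rnorm(5), 2004, 5), r(rnorm(5), 2004, 6),
                   r(rnorm(5), 2005, 5), r(rnorm(5), 2005, 6))
  ov <- average_maps(balanced, "overall")
  pooled <- Reduce(`+`, lapply(balanced, function(x) x$values)) / 4
  expect_equal(ov$values, pooled)
  unbalanced <- balanced[1:3]
  ov2 <- average_maps(unbalanced, "overall")
  pooled2 <- Reduce(`+`, lapply(unbalanced, function(x) x$values)) / 3
  expect_false(isTRUE(all.equal(ov2$values, pooled2)))
})

test_that("decile classes come from the pooled distribution", {
  r <- prediction_raster(1:100, "krill", 2004, 5)
  dc <- decile_scale(r)
  expect_equal(dc$classes[[1]][1:10], rep(1L, 10))
  expect_equal(dc$classes[[1]][91:100], rep(10L, 10))
  expect_equal(sort(unique(dc$classes[[1]])), 1:10)
  # identical rasters get identical class maps
  dc2 <- decile_scale(list(r, r))
  expect_identical(dc2$classes[[1]], dc2$classes[[2]])
  # rank invariance under monotone transforms
  r2 <- prediction_raster(exp((1:100) / 20), "krill", 2004, 5)
  expect_identical(decile_scale(r2)$classes[[1]], dc$classes[[1]])
  # constant raster collapses with a warning
  expect_warning(dcc <- decile_scale(prediction_raster(rep(2, 30), "k", 1, 1)),
                 "constant")
  expect_equal(unique(dcc$classes[[1]]), 1L)
  # pooling differs from per-map scaling: a low map sits in low classes
  lo <- prediction_raster(1:10, "krill", 2004, 5)
  hi <- prediction_raster(91:100, "krill", 2004, 6)
  dcp <- decile_scale(list(lo, hi))
  expect_true(all(dcp$classes[[1]] <= 5))
  expect_true(all(dcp$classes[[2]] >= 6))
})

test_that("prediction rasters from a recovered fit track the truth surface", {
  grid <- make_study_grid(c(30, 20), 1)
  truth <- default_truth_spec(1)
  cl <- make_climate_table(2004:2009, seed = 4)
  cruises <- make_cruises(2004:2009, c(5, 6, 7, 9), cl)
  bins <- simulate_observations(grid, cruises, truth, seed = 6,
                                transect_spacing_km = 3)
  des <- design_spec("humpback_count", truth$humpback$terms,
                     offset = "survey_area", family = "negbin")
  f <- fit_design(des, bins)
  gdat <- grid
  fseed <- whalekrill:::derive_seeds(21, length(truth$fields))
  for (k in seq_along(truth$fields)) {
    fp <- truth$fields[[k]]
    gdat[[names(truth$fields)[k]]] <- simulate_field(
      grid, fp$sill, fp$range_km, fp$nugget, fp$trend_coeffs, seed = fseed[k])
  }
  for (cl2 in grep("_lag", names(cruises), value = TRUE)) {
    gdat[[cl2]] <- cruises[[cl2]][1]
  }
  pred <- predict_grid(f, gdat)
  expect_gt(cor(pred$values, truth_expected(truth$humpback, gdat)), 0.95)
})
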