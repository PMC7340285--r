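# Variograms, ordinary kriging, LOOCV quality gates, detrending.

test_that("empirical variogram matches hand-computed semivariances", {
  # two points, values 0 and 2 -> single bin gamma = 0.5 * (2-0)^2 = 2
  emp <- expect_quiet_pass(
    empirical_variogram(cbind(c(0, 1), c(0, 0)), c(0, 2), n_lags = 1,
                        max_lag = 2))
  expect_equal(emp$gamma, 2)
  expect_equal(emp$np, 1L)
  # constant field -> gamma = 0 at every lag
  set.seed(1)
  pts <- cbind(runif(20) * 10, runif(20) * 10)
  emp0 <- expect_quiet_pass(empirical_variogram(pts, rep(3, 20)))
  expect_true(all(emp0$gamma == 0))
  # pure-nugget white noise -> roughly flat at the nugget across lags
  set.seed(2)
  ptsn <- cbind(runif(400) * 20, runif(400) * 20)
  vn <- rnorm(400, sd = sqrt(0.5))
  empn <- expect_quiet_pass(empirical_variogram(ptsn, vn))
  expect_lt(max(abs(empn$gamma - 0.5)), 0.15)
  expect_error(empirical_variogram(cbind(1, 1), 1), ">= 2")
})

test_that("variogram fitting recovers simulated exponential parameters", {
  sim <- sim_krige_points(250, seed = 3, extent = c(40, 40), sill = 1,
                          range_km = 5, nugget = 0)
  emp <- expect_quiet_pass(empirical_variogram(sim$points, sim$values))
  vg <- expect_quiet_pass(fit_variogram(emp, families = "exponential"))
  expect_equal(vg$family, "exponential")
  expect_lt(abs(vg$sill - 1) / 1, 0.25)
  expect_lt(abs(vg$range - 5) / 5, 0.5)
  # single candidate family is returned as such
  vg2 <- expect_quiet_pass(fit_variogram(emp, families = "spherical"))
  expect_equal(vg2$family, "spherical")
})

test_that("pure-nugget data collapse to a nugget model and the global mean", {
  set.seed(4)
  pts <- cbind(runif(120) * 20, runif(120) * 20)
  vals <- rnorm(120, mean = 5, sd = 1)
  emp <- expect_quiet_pass(empirical_variogram(pts, vals))
  vg <- expect_quiet_pass(fit_variogram(emp, points = pts, values = vals))
  # the kriging limit: with no real structure, leave-one-out predictions
  # carry far less variance than the data (they shrink to the mean)
  cv <- whalekrill:::krige_loocv(pts, vals, vg)
  expect_lt(sd(cv), 0.4 * sd(vals))
  # kriging at far targets -> global mean
  far <- cbind(c(100, 200), c(100, 150))
  ok <- expect_quiet_pass(ordinary_krige(pts, vals, vg, far))
  expect_equal(ok$pred, rep(mean(vals), 2), tolerance = 0.05)
})

test_that("kriging is an exact interpolator with zero variance at data", {
  sim <- sim_krige_points(60, seed = 5)
  vg <- structure(list(family = "exponential", nugget = 0.1, sill = 1.1,
                       range = 6), class = "wk_vgm")
  ok <- ordinary_krige(sim$points, sim$values, vg, sim$points)
  expect_lt(max(abs(ok$pred - sim$values)), 1e-8)
  expect_lt(max(ok$var), 1e-8)
  # constant data predict the constant anywhere
  okc <- ordinary_krige(sim$points, rep(4, 60), vg,
                        cbind(c(1, 15, 40), c(1, 10, 30)))
  expect_equal(okc$pred, rep(4, 3), tolerance = 1e-8)
})

test_that("pure-nugget kriging at a fresh target is the global mean (hand case)", {
  vg <- structure(list(family = "nugget", nugget = 1, sill = 1, range = 1),
                  class = "wk_vgm")
  ok <- ordinary_krige(cbind(c(0, 1, 0), c(0, 0, 1)), c(0, 1, 1), vg, cbind(1, 1))
  expect_equal(ok$pred, 2 / 3)
})

test_that("duplicate locations are averaged, not left to break the solver", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))
  vg <- structure(list(family = "exponential", nugget = 0, sill = 1,
                       range = 2), class = "wk_vgm")
  expect_message(ok <- ordinary_krige(pts, c(0, 2, 1, 1), vg, cbind(0, 0)),
                 "averaged")
  expect_equal(ok$pred, 1) # mean of the duplicated 0 and 2
})

test_that("kriging variance grows with distance from the data", {
  sim <- sim_krige_points(50, seed = 6, extent = c(10, 10))
  vg <- structure(list(family = "exponential", nugget = 0.05, sill = 1,
                       range = 4), class = "wk_vgm")
  targets <- cbind(seq(10, 40, by = 5), 5) # walking away from the data
  ok <- ordinary_krige(sim$points, sim$values, vg, targets)
  expect_true(all(diff(ok$var) >= -1e-9))
})

test_that("fast leave-one-out equals re-solving without each point", {
  sim <- sim_krige_points(40, seed = 7)
  vg <- structure(list(family = "exponential", nugget = 0.1, sill = 1,
                       range = 5), class = "wk_vgm")
  expect_equal(whalekrill:::krige_loocv(sim$points, sim$values, vg),
               whalekrill:::krige_loocv_naive(sim$points, sim$values, vg),
               tolerance = 1e-10)
})

test_that("QC gates: constant fields pass, fine-scale bimodal fields fail", {
  pts <- cbind(runif(30) * 10, runif(30) * 10)
  vgn <- structure(list(family = "nugget", nugget = 0, sill = 0, range = 1),
                   class = "wk_vgm")
  qc <- loocv_qc(pts, rep(2, 30), vgn)
  expect_true(qc$passed)
  expect_true(qc$constant_field)
  expect_equal(qc$pct_rmse, 0)
  # unpredictable bimodal fine-scale structure trips the %RMSE gate
  set.seed(8)
  ptsb <- cbind(runif(60) * 30, runif(60) * 20)
  vb <- sample(c(-1, 1), 60, replace = TRUE) + rnorm(60, 0, 0.05)
  empb <- expect_quiet_pass(empirical_variogram(ptsb, vb))
  vgb <- expect_quiet_pass(fit_variogram(empb, points = ptsb, values = vb))
  qcb <- loocv_qc(ptsb, vb, vgb)
  expect_gt(qcb$pct_rmse, 30)
  expect_false(qcb$passed)
})

test_that("a well-specified field passes the QC gates", {
  sim <- sim_krige_points(200, seed = 9)
  emp <- expect_quiet_pass(empirical_variogram(sim$points, sim$values))
  vg <- expect_quiet_pass(fit_variogram(emp, points = sim$points,
                                        values = sim$values))
  qc <- loocv_qc(sim$points, sim$values, vg)
  expect_true(qc$passed)
})

test_that("detrending reproduces an exact quadratic and enforces its precondition", {
  set.seed(10)
  pts <- cbind(runif(40) * 10, runif(40) * 10)
  quad <- function(p) 1 + 0.5 * p[, 1] - 0.2 * p[, 2] + 0.05 * p[, 1]^2 +
    0.03 * p[, 2]^2 - 0.04 * p[, 1] * p[, 2]
  vals <- quad(pts)
  targets <- cbind(runif(10) * 10, runif(10) * 10)
  dt <- expect_quiet_pass(detrend_krige(pts, vals, targets))
  expect_lt(max(abs(dt$pred - quad(targets))), 1e-6)
  expect_true(dt$qc$detrended)
  # refusing to detrend a surface that already passes
  sim <- sim_krige_points(100, seed = 11)
  emp <- expect_quiet_pass(empirical_variogram(sim$points, sim$values))
  vg <- expect_quiet_pass(fit_variogram(emp, points = sim$points,
                                        values = sim$values))
  qc <- loocv_qc(sim$points, sim$values, vg)
  expect_true(qc$passed)
  expect_error(detrend_krige(sim$points, sim$values, sim$points[1:3, ],
                             qc_plain = qc), "precondition")
})

test_that("detrended kriging passes QC on a strongly trended field", {
  set.seed(12)
  pts <- cbind(runif(120) * 30, runif(120) * 20)
  g <- data.frame(x = pts[, 1], y = pts[, 2])
  vals <- 0.2 * (pts[, 1] - 15)^2 +
    simulate_field(g, sill = 0.5, range_km = 5, nugget = 0.05, seed = 13)
  dt <- expect_quiet_pass(detrend_krige(pts, vals, pts[1:5, , drop = FALSE]))
  expect_true(dt$qc$passed)
})

test_that("krige_surface gates, falls back, and keeps variances non-negative", {
  sim <- sim_krige_points(120, seed = 14)
  grid <- make_study_grid(c(10, 10), 1)
  surf <- expect_quiet_pass(krige_surface(sim$points, sim$values,
                                          grid[, c("x", "y")]))
  expect_s3_class(surf, "wk_surface")
  expect_length(surf$pred, 100)
  expect_true(all(surf$var >= 0))
  expect_true(surf$qc$passed)
  expect_false(surf$detrended)
})
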