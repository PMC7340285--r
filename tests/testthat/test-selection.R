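# Univariate screening, backward stepwise and year interactions.

sim_screen_data <- function(n, seed, kind = c("quadratic", "noise", "lag3")) {
  kind <- match.arg(kind)
  set.seed(seed)
  d <- data.frame(x = rnorm(n))
  if (kind == "lag3") {
    for (l in 0:3) d[[paste0("c_lag", l)]] <- rnorm(n)
    d$y <- rnbinom(n, size = 2, mu = exp(0.5 + 0.5 * d$c_lag3))
  } else if (kind == "quadratic") {
    d$y <- rnbinom(n, size = 2, mu = exp(0.5 + 0.5 * d$x - 0.4 * d$x^2))
  } else {
    d$y <- rnbinom(n, size = 2, mu = exp(0.5))
  }
  d
}

test_that("screening recovers a quadratic response most of the time", {
  hits <- sapply(1:25, function(s) {
    d <- sim_screen_data(2000, s, "quadratic")
    sc <- suppressWarnings(screen_variable("x", "oceanographic", "y",
                                           "negbin", d))
    sc$included && sc$term$transform == "quadratic"
  })
  expect_gte(mean(hits), 0.8)
})

test_that("a pure-noise covariate is usually excluded", {
  # four ladder candidates at alpha = 0.05 give a familywise inclusion
  # rate near 1 - 0.95^4 ~ 18.5%; assert exclusion well above chance
  inc <- sapply(1:40, function(s) {
    d <- sim_screen_data(2000, s + 100, "noise")
    suppressWarnings(screen_variable("x", "oceanographic", "y", "negbin",
                                     d))$included
  })
  expect_gte(mean(!inc), 0.70)
})

test_that("climate screening picks the driving lag", {
  hits <- sapply(1:15, function(s) {
    d <- sim_screen_data(2000, s + 200, "lag3")
    sc <- suppressWarnings(screen_variable("c", "climate", "y", "negbin", d))
    sc$included && !is.na(sc$term$lag) && sc$term$lag == 3
  })
  expect_gt(mean(hits), 0.5)
})

test_that("distance screening tries all four transforms", {
  set.seed(5)
  n <- 1500
  d <- data.frame(dist = runif(n, 0, 40))
  d$y <- rnbinom(n, size = 2, mu = exp(1.5 - 0.8 * log1p(d$dist)))
  sc <- suppressWarnings(screen_variable("dist", "distance", "y", "negbin", d))
  expect_true(sc$included)
  expect_setequal(unique(sc$candidates$form),
                  c("linear", "quadratic", "log", "invlog"))
  expect_equal(sc$term$transform, "log")
})

test_that("stepwise keeps the truth, prunes noise and respects marginality", {
  set.seed(7)
  n <- 3000
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), z1 = rnorm(n), z2 = rnorm(n))
  d$y <- rnbinom(n, size = 2, mu = exp(0.5 + 0.4 * d$x1 - 0.3 * d$x1^2 +
                                         0.3 * d$x2))
  full <- design_spec("y", list(term_spec("x1", "quadratic"), term_spec("x2"),
                                term_spec("z1"), term_spec("z2")),
                      family = "negbin")
  sp <- suppressWarnings(backward_stepwise(full, d))
  labs <- vapply(sp$final_design$terms,
                 function(t) paste0(t$covariate, ":", t$transform), "")
  expect_true("x1:quadratic" %in% labs)
  expect_true("x2:linear" %in% labs)
  # marginality: no path model carries x1^2 without x1 (drop is top-down),
  # encoded by transforms only ever stepping down the ladder
  expect_true(all(grepl("dropped|NA|z1|z2|x2|x1", sp$path$dropped[-1])))
  # the final fit is fully significant
  expect_true(all(whalekrill:::droppable_pvalues(sp$final_fit) < 0.05))
})

test_that("single significant term yields a length-1 path", {
  set.seed(8)
  d <- data.frame(x = rnorm(1000))
  d$y <- rnbinom(1000, size = 2, mu = exp(0.5 + 0.8 * d$x))
  sp <- backward_stepwise(design_spec("y", list(term_spec("x")),
                                      family = "negbin"), d)
  expect_equal(nrow(sp$path), 1)
  expect_equal(sp$rule, "dAIC>2")
})

test_that("the dAIC-2 / BIC rule takes the right branch on fixtures", {
  # clear winner: lowest AIC more than 2 below the runner-up
  r1 <- apply_aic_bic_rule(aic = c(110, 100, 107), bic = c(112, 109, 108))
  expect_equal(r1$index, 2)
  expect_equal(r1$rule, "dAIC>2")
  # two models 1.5 AIC apart: BIC tie-break decides
  r2 <- apply_aic_bic_rule(aic = c(100, 101.5), bic = c(106, 103))
  expect_equal(r2$index, 2)
  expect_equal(r2$rule, "BIC tie-break")
  # tie-break only consults models within 2 AIC of the best
  r3 <- apply_aic_bic_rule(aic = c(100, 101.5, 109), bic = c(106, 103, 95))
  expect_equal(r3$index, 2)
})

test_that("year interactions are detected when present and rare when absent", {
  sim_year <- function(s, interact) {
    set.seed(s)
    n <- 1500
    d <- data.frame(x = rnorm(n), ci = rnorm(n),
                    year = sample(2004:2006, n, replace = TRUE))
    slope <- if (interact) c(0.1, 0.5, -0.3)[d$year - 2003] else 0.25
    d$y <- rnbinom(n, size = 2, mu = exp(0.5 + 0.4 * d$x + slope * d$ci))
    d
  }
  base <- design_spec("y", list(term_spec("x"), term_spec("ci")),
                      family = "negbin")
  hits <- sapply(1:12, function(s) {
    yt <- year_interaction_test(base, "ci", sim_year(s, TRUE))
    yt$table$retained[yt$table$var == "ci"]
  })
  expect_gte(mean(hits), 0.8)
  false_pos <- sapply(1:12, function(s) {
    yt <- year_interaction_test(base, "ci", sim_year(s + 50, FALSE))
    yt$table$retained[yt$table$var == "ci"]
  })
  expect_lte(mean(false_pos), 0.25)
  # contract: the base model must contain the candidate
  expect_error(year_interaction_test(base, "depth", sim_year(1, FALSE)),
               "lacks static")
})

test_that("screen_all assembles a full design over included covariates", {
  set.seed(20)
  n <- 1500
  d <- data.frame(temp = rnorm(n, 12, 1), dist = runif(n, 0, 30),
                  noise = rnorm(n))
  d$y <- rnbinom(n, size = 2, mu = exp(0.3 + 0.6 * (d$temp - 12) -
                                         0.05 * d$dist))
  sc <- suppressWarnings(screen_all(
    c(temp = "oceanographic", dist = "distance", noise = "oceanographic"),
    "y", "negbin", d))
  labs <- vapply(sc$design$terms, function(t) t$covariate, "")
  expect_true(all(c("temp", "dist") %in% labs))
  expect_length(sc$screens, 3)
})
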