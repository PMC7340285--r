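# Independent oracles and small data generators shared across tests.

# Brute-force Getis-Ord Gi* straight from the formula, triple loops, no
# vectorisation shared with the implementation.
gstar_bruteforce <- function(values, coords, band, self = TRUE) {
  n <- length(values)
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    wsum <- 0; w2sum <- 0; wx <- 0
    for (j in seq_len(n)) {
      d <- sqrt((coords[i, 1] - coords[j, 1])^2 + (coords[i, 2] - coords[j, 2])^2)
      w <- if (i == j) as.numeric(self) else as.numeric(d <= band)
      wsum <- wsum + w
      w2sum <- w2sum + w^2
      wx <- wx + w * values[j]
    }
    z[i] <- (wx - xbar * wsum) / (S * sqrt((n * w2sum - wsum^2) / (n - 1)))
  }
  z
}

# NB2 log-likelihood evaluated from first principles (no dnbinom).
nb2_loglik_manual <- function(y, mu, theta) {
  sum(lgamma(y + theta) - lgamma(theta) - lfactorial(y) +
        theta * (log(theta) - log(theta + mu)) +
        y * (log(mu) - log(theta + mu)))
}

# Hurdle data generator at given truth.
sim_hurdle_data <- function(n, seed, gamma = c(-0.5, 1.0),
                            beta = c(2, 0.8), theta = 1.5) {
  set.seed(seed)
  x <- rnorm(n)
  pr <- plogis(gamma[1] + gamma[2] * x)
  pres <- rbinom(n, 1, pr)
  mu <- exp(beta[1] + beta[2] * x)
  p0 <- dnbinom(0, size = theta, mu = mu)
  u <- runif(n, p0, 1)
  y <- ifelse(pres == 1, qnbinom(pmin(u, 1 - 1e-16), size = theta, mu = mu), 0L)
  data.frame(y = as.integer(y), x = x)
}

# Scattered-point exponential GRF sample for kriging tests.
sim_krige_points <- function(n, seed, extent = c(30, 20), sill = 1,
                             range_km = 6, nugget = 0.1) {
  set.seed(seed)
  pts <- cbind(x = runif(n) * extent[1], y = runif(n) * extent[2])
  vals <- simulate_field(as.data.frame(pts), sill = sill, range_km = range_km,
                         nugget = nugget, seed = seed + 10000)
  list(points = pts, values = vals)
}

expect_quiet_pass <- function(expr) suppressWarnings(suppressMessages(expr))
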