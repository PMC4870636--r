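test_that("intercept-only Poisson fit has the closed-form solution", {
  set.seed(10)
  y <- rpois(30, 5)
  off <- log(runif(30, 50, 150))
  fit <- fit_poisson(y, NULL, off)
  expect_equal(unname(coef(fit)[1]), log(sum(y) / sum(exp(off))),
               tolerance = 1e-8)
  expect_equal(sum(fitted(fit)), sum(y), tolerance = 1e-8)
  # fitted shares proportional to offsets
  expect_equal(fitted(fit) / exp(off), rep(sum(y) / sum(exp(off)), 30),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a saturated two-area Poisson fit reproduces the data", {
  y <- c(2, 4)
  fit <- fit_poisson(y, matrix(c(0, 1), 2, dimnames = list(NULL, "g")),
                     c(0, 0))
  expect_equal(unname(fitted(fit)), y, tolerance = 1e-8)
})

test_that("Poisson regression recovers known coefficients", {
  set.seed(42)
  n <- 500
  x <- rnorm(n)
  off <- log(runif(n, 1000, 3000))
  eta <- off - 5.7 + 0.12 * x
  y <- rpois(n, exp(eta))
  fit <- fit_poisson(y, matrix(x, n, dimnames = list(NULL, "x")), off)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - (-5.7)),
            3 * fit$se[["(Intercept)"]])
  expect_lt(abs(coef(fit)[["x"]] - 0.12), 3 * fit$se[["x"]])
})

test_that("rank-deficient designs are rejected", {
  set.seed(1)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x)
  expect_error(fit_poisson(rpois(20, 3), X, rep(0, 20)), "rank deficient")
})

test_that("negative binomial fit approaches Poisson on equidispersed data", {
  set.seed(5)
  n <- 300
  off <- log(runif(n, 500, 1500))
  y <- rpois(n, exp(off - 6))
  fp <- fit_poisson(y, NULL, off)
  fnb <- fit_negbin(y, NULL, off)
  expect_lt(abs(fnb$loglik - fp$loglik), 0.5)
  expect_gt(fnb$theta, 100)
  expect_equal(unname(coef(fnb)), unname(coef(fp)), tolerance = 1e-3)
  expect_equal(sum(fitted(fnb)), sum(y), tolerance = 1e-4)
  # AIC counts the dispersion parameter
  expect_equal(fnb$aic, -2 * fnb$loglik + 2 * 2, tolerance = 1e-8)
})

test_that("negative binomial recovers a known dispersion", {
  set.seed(6)
  n <- 500
  off <- log(runif(n, 800, 2000))
  mu <- exp(off - 5.5)
  y <- rnbinom(n, size = 2, mu = mu)
  fit <- fit_negbin(y, NULL, off)
  se_theta <- fit$fit$SE.theta
  expect_lt(abs(fit$theta - 2), 3 * se_theta)
})

test_that("Dean's statistic follows its defining formula", {
  set.seed(30)
  n <- 56
  off <- log(runif(n, 1000, 3000))
  y <- rpois(n, exp(off - 5.7))
  fit <- fit_poisson(y, NULL, off)
  d <- dean_test(fit)
  mu <- fitted(fit)
  expect_equal(d$statistic, sum((y - mu)^2 - y) / sqrt(2 * sum(mu^2)),
               tolerance = 1e-12)
  # perfect fit (y == mu) forces a negative statistic and no rejection
  ysat <- c(2, 4)
  suppressWarnings(dsat <- dean_test(
    fit_poisson(ysat, matrix(c(0, 1), 2, dimnames = list(NULL, "g")),
                c(0, 0))))
  expect_lt(dsat$statistic, 0)
  expect_false(dsat$decision)
})

test_that("Dean's null upper tail is calibrated at several levels", {
  set.seed(32)
  n <- 56
  off <- log(runif(n, 1000, 3000))
  stats_null <- replicate(600, {
    y <- rpois(n, exp(off - 5.7))
    dean_test(fit_poisson(y, NULL, off))$statistic
  })
  # one-sided rejection regions drive the test decision; check both the
  # 5% and 10% upper tails against binomial Monte-Carlo bands
  expect_lt(abs(mean(stats_null > qnorm(0.95)) - 0.05), 0.03)
  expect_lt(abs(mean(stats_null > qnorm(0.90)) - 0.10), 0.04)
})

test_that("Dean's test has power against negative binomial dispersion", {
  set.seed(31)
  n <- 56
  off <- log(runif(n, 1000, 3000))
  rej <- replicate(200, {
    y <- rnbinom(n, size = 1, mu = exp(off - 5.7))
    dean_test(fit_poisson(y, NULL, off))$decision
  })
  expect_gt(mean(rej), 0.9)
})

test_that("Moran's I matches a brute-force double-loop evaluation", {
  set.seed(40)
  for (rep in 1:5) {
    nr <- sample(2:4, 1); nc <- sample(2:5, 1)
    lat <- grid_lattice(nr, nc, sample(c("rook", "queen"), 1))
    n <- lat$n
    x <- rnorm(n)
    z <- x - mean(x)
    num <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      num <- num + lat$W[i, j] * z[i] * z[j]
    }
    I_brute <- (n / sum(lat$W)) * num / sum(z^2)
    expect_equal(moran_test(x, lat)$statistic, I_brute, tolerance = 1e-12)
  }
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(41)
  # ape row-standardizes its weights; on a regular graph (a ring: every
  # area has exactly 2 neighbours) that is a uniform rescaling, to which
  # Moran's I and its randomization variance are invariant, so the two
  # implementations must agree exactly there.
  n <- 30
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    W[i, (i %% n) + 1] <- 1
    W[(i %% n) + 1, i] <- 1
  }
  x <- rnorm(n)
  ours <- moran_test(x, W, alternative = "two.sided")
  theirs <- ape::Moran.I(x, W, scaled = FALSE, alternative = "two.sided")
  expect_equal(ours$statistic, theirs$observed, tolerance = 1e-10)
  expect_equal(ours$expectation, theirs$expected, tolerance = 1e-10)
  expect_equal(sqrt(ours$variance), theirs$sd, tolerance = 1e-10)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-8)
})

test_that("Moran's I has the known closed-form special cases", {
  # null expectation
  expect_equal(moran_test(rnorm(53), grid_lattice(53, 1))$expectation,
               -1 / 52)
  # perfect checkerboard on a 4x4 rook grid: I = -1
  lat <- grid_lattice(4, 4, "rook")
  chk <- (((0:15) %/% 4) + ((0:15) %% 4)) %% 2
  expect_equal(moran_test(as.numeric(chk), lat)$statistic, -1,
               tolerance = 1e-12)
  expect_error(moran_test(rep(1, 16), lat), "constant")
})

test_that("permutation p-values track the normal approximation", {
  set.seed(43)
  lat <- grid_lattice(7, 8)
  x <- as.numeric(scale(seq_len(lat$n) %/% 8)) + rnorm(lat$n, 0, 0.7)
  pn <- moran_test(x, lat, method = "normal")$p_value
  pp <- moran_test(x, lat, method = "permutation", nperm = 9999)$p_value
  expect_lt(abs(pn - pp), 0.02)
})

test_that("forward selection returns the base model when nothing helps", {
  set.seed(50)
  lat <- grid_lattice(7, 8)
  off <- log(runif(lat$n, 1000, 3000))
  y <- rpois(lat$n, exp(off - 5.7))
  cand <- simulate_covariates(lat, 0)
  sel <- forward_select(y, NULL, cand, off)
  # with pure-noise candidates the trace has at most the first round
  expect_lte(max(sel$trace$round), 1)
  expect_equal(nrow(sel$trace), 1 + ncol(cand))
})

test_that("forward selection finds the active covariate", {
  set.seed(51)
  lat <- grid_lattice(7, 8)
  hits <- replicate(200, {
    off <- log(runif(lat$n, 1000, 3000))
    X <- simulate_covariates(lat, 0)
    y <- rpois(lat$n, exp(off - 5.7 + 0.2 * X[, "ECON"]))
    sel <- forward_select(y, NULL, X, off)
    length(sel$selected) >= 1 && sel$selected[1] == "ECON"
  })
  expect_gt(mean(hits), 0.9)
})

test_that("the selection trace has the combinatorial shape of the procedure", {
  set.seed(52)
  lat <- grid_lattice(7, 8)
  off <- log(runif(lat$n, 1000, 3000))
  X <- simulate_covariates(lat, 0)
  # strong effects on all three so every round proceeds
  y <- rpois(lat$n, exp(off - 5.7 + 0.5 * X[, 1] + 0.4 * X[, 2] +
                          0.3 * X[, 3]))
  sel <- forward_select(y, NULL, X, off)
  counts <- table(sel$trace$round)
  expect_equal(unname(counts[c("1", "2", "3")]), c(3L, 2L, 1L),
               ignore_attr = TRUE)
})

test_that("log-likelihood is monotone in nested models", {
  set.seed(53)
  lat <- grid_lattice(7, 8)
  off <- log(runif(lat$n, 1000, 3000))
  X <- simulate_covariates(lat, 0)
  y <- rpois(lat$n, exp(off - 5.7 + 0.2 * X[, 1]))
  f0 <- fit_poisson(y, NULL, off)
  f1 <- fit_poisson(y, X[, 1, drop = FALSE], off)
  f2 <- fit_poisson(y, X[, 1:2], off)
  expect_gte(f1$loglik, f0$loglik)
  expect_gte(f2$loglik, f1$loglik)
})
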