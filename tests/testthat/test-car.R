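test_that("CAR precision matrices obey the algebraic identities", {
  lat <- grid_lattice(3, 3)
  n <- lat$n
  D <- diag(rowSums(lat$W))
  expect_equal(car_precision("leroux", lat, rho = 0), diag(n))
  expect_equal(car_precision("leroux", lat, rho = 1), D - lat$W)
  expect_equal(car_precision("ind", lat), diag(n))
  expect_equal(car_precision("iar", lat), D - lat$W)
  bym <- car_precision("bym", lat)
  expect_equal(bym$structured, D - lat$W)
  expect_equal(bym$unstructured, diag(n))
})

test_that("the 3-area path graph Leroux precision matches the hand result", {
  W <- toy3()$W
  Q <- car_precision("leroux", W, rho = 0.5)
  expect_equal(Q, matrix(c(1, -0.5, 0,
                           -0.5, 1.5, -0.5,
                           0, -0.5, 1), 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("fixed seeds give identical chains", {
  ds <- synthetic_area_data(seed = 42)
  lat <- attr(ds, "lattice")
  args <- list(ds$y, as.matrix(ds[, "ECON", drop = FALSE]), log(ds$n), lat,
               structure = "leroux",
               mcmc = mcmc_control(500, 1000, thin = 2), seed = 99)
  f1 <- do.call(fit_car, args)
  f2 <- do.call(fit_car, args)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$fitted_samples, f2$fitted_samples)
})

test_that("with the random effect switched off the posterior matches ML", {
  # Bernstein-von Mises: flat prior, no overdispersion channel
  ds <- synthetic_area_data(seed = 5)
  X <- as.matrix(ds[, "ECON", drop = FALSE])
  ml <- fit_poisson(ds$y, X, log(ds$n))
  fit <- fit_car(ds$y, X, log(ds$n), attr(ds, "lattice"), structure = "ind",
                 mcmc = mcmc_control(3000, 30000, thin = 5,
                                     fix_sigma2 = 1e-8), seed = 3)
  expect_lt(max(abs(coef(fit) - coef(ml))), 0.02)
})

test_that("MCMC posterior means match grid integration on the 3-area toy", {
  toy <- toy3()
  oracle <- grid_posterior_mean(toy$y, toy$offset)
  fit <- fit_car(toy$y, NULL, toy$offset, toy$W, structure = "ind",
                 mcmc = mcmc_control(3000, 60000, thin = 10,
                                     fix_sigma2 = 1e-8), seed = 4)
  b0 <- fit$chains$beta[, 1]
  expect_lt(abs(mean(b0) - oracle), 3 * mcse(b0) + 1e-3)
})

test_that("posterior fitted values reproduce observed totals", {
  ds <- synthetic_area_data(seed = 8)
  fit <- fit_car(ds$y, as.matrix(ds[, "ECON", drop = FALSE]), log(ds$n),
                 attr(ds, "lattice"), structure = "leroux",
                 mcmc = quick_mcmc(), seed = 2)
  expect_lt(abs(sum(fitted(fit)) - sum(ds$y)) / sum(ds$y), 0.05)
  expect_gte(fit$p_d, 0)
  # credible intervals contain the posterior median
  med <- apply(fit$chains$beta, 2, stats::median)
  expect_true(all(fit$or_table$ci_low <= exp(med) &
                    exp(med) <= fit$or_table$ci_high))
})

test_that("DIC of the Leroux model stays near IND's on independent data", {
  set.seed(60)
  diffs <- replicate(10, {
    ds <- synthetic_area_data(truth = generative_truth(
      beta = c(ECON = 0), rho = 0, tau2 = 0, sigma2 = 0))
    lat <- attr(ds, "lattice")
    m <- mcmc_control(2000, 6000, thin = 3)
    fl <- fit_car(ds$y, NULL, log(ds$n), lat, "leroux", mcmc = m, seed = 1)
    fi <- fit_car(ds$y, NULL, log(ds$n), lat, "ind", mcmc = m, seed = 1)
    fl$dic - fi$dic
  })
  expect_lt(abs(mean(diffs)), 3)
})

test_that("Geweke Z is zero for identical segments and large for a trend", {
  seg <- rnorm(100)
  chain <- c(seg, rnorm(400), rep(seg, 5))
  expect_equal(geweke_z(chain), 0, tolerance = 1e-10)
  expect_gt(abs(geweke_z(seq(0, 1, length.out = 2000))), 1.96)
  expect_error(geweke_z(rep(1, 500)), "zero-variance")
  expect_error(geweke_z(rnorm(50)), "too short")
})

test_that("Geweke Z is calibrated on iid chains", {
  set.seed(61)
  zs <- replicate(300, geweke_z(rnorm(10000)))
  inside <- mean(abs(zs) < 1.96)
  expect_gt(inside, 0.90)
  expect_lt(inside, 0.99)
})

test_that("Geweke Z agrees broadly with the reference implementation", {
  skip_if_not_installed("coda")
  set.seed(62)
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), 5000))
  ours <- geweke_z(x)
  theirs <- unname(coda::geweke.diag(coda::mcmc(x))$z)
  expect_lt(abs(ours - theirs), 0.6)
  expect_equal(sign(ours), sign(theirs))
})

test_that("exceedance probabilities and hotspot flags follow the chains", {
  E <- c(10, 10)
  up <- fake_carfit(matrix(c(rep(15, 100), rep(12, 100)), 100, 2), E)
  rep_up <- smoothed_rr(up)
  expect_equal(rep_up$exceedance, c(1, 1))
  expect_true(all(rep_up$hotspot))
  # symmetric posterior of log RR about zero: exceedance ~ 0.5, no flag
  set.seed(63)
  lrr <- rnorm(4000)
  sym <- fake_carfit(matrix(10 * exp(c(lrr, -lrr)), 8000, 1), E = 10)
  rep_sym <- smoothed_rr(sym)
  expect_equal(rep_sym$exceedance, 0.5, tolerance = 1e-12)
  expect_false(rep_sym$hotspot)
  # deterministic function of chains and cutoff
  expect_identical(smoothed_rr(up), smoothed_rr(up))
  expect_false(any(smoothed_rr(up, cutoff = 1.01)$hotspot))
})

test_that("thinning leaves exceedance probabilities unbiased", {
  set.seed(64)
  samples <- matrix(exp(rnorm(8000, 0.05, 0.4)) * 10, 8000, 1)
  full <- smoothed_rr(fake_carfit(samples, 10))$exceedance
  thin <- smoothed_rr(fake_carfit(samples[seq(1, 8000, 4), , drop = FALSE],
                                  10))$exceedance
  expect_lt(abs(full - thin), 0.05)
})

test_that("chains export to CSV with one column per scalar", {
  ds <- synthetic_area_data(seed = 13)
  fit <- fit_car(ds$y, as.matrix(ds[, "ECON", drop = FALSE]), log(ds$n),
                 attr(ds, "lattice"), structure = "leroux",
                 mcmc = mcmc_control(500, 1000, thin = 2), seed = 1,
                 E = ds$E)
  f <- tempfile(fileext = ".csv")
  write_chains_csv(fit, f)
  chains <- utils::read.csv(f)
  expect_equal(nrow(chains), 500)
  expect_true(all(c("beta..Intercept.", "beta.ECON", "tau2", "rho",
                    "deviance") %in% names(chains)))
  fj <- tempfile(fileext = ".json")
  write_fit_json(fit, fj)
  meta <- jsonlite::read_json(fj)
  expect_equal(meta$structure, "leroux")
  expect_true(is.numeric(meta$dic))
  unlink(c(f, fj))
})

test_that("degenerate CAR inputs error cleanly", {
  toy <- toy3()
  expect_error(fit_car(toy$y, NULL, c(1, 2), toy$W), "aligned")
  expect_error(fit_car(toy$y, NULL, c(Inf, 0, 0), toy$W), "finite")
  W0 <- matrix(0, 3, 3)
  expect_error(fit_car(toy$y, NULL, toy$offset, W0, structure = "iar"),
               "isolated")
})
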