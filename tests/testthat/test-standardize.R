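test_that("stratum prevalences reproduce the catchment table cells", {
  s <- collapse_strata(table1_fixture())
  pr <- stratum_prevalence(s$cases, s$population)
  prev <- setNames(pr$prevalence, s$stratum)
  expect_equal(round(prev[["40-54"]], 2), 0.64)
  expect_equal(round(prev[["M25-39"]], 2), 0.58)
  expect_equal(round(prev[["18-24"]], 2), 0.12)
  expect_true(all(pr$ci_low <= pr$prevalence & pr$prevalence <= pr$ci_high))
})

test_that("zero cases give zero prevalence; zero population errors", {
  expect_equal(stratum_prevalence(0, 500)$prevalence, 0)
  expect_error(stratum_prevalence(c(1, 2), c(100, 0)), "stratum 2")
})

test_that("expected counts satisfy the internal standardization identity", {
  # on the fixture treated as one area
  s <- collapse_strata(table1_fixture())
  E1 <- expected_counts(matrix(s$population, 1), s$cases / s$population)
  expect_equal(E1, sum(s$cases), tolerance = 1e-9)
  # on synthetic datasets of various shapes and seeds
  for (seed in c(1, 2, 3)) {
    ds <- synthetic_area_data(seed = seed)
    expect_lt(abs(sum(ds$E) - sum(ds$y)), 1e-9)
  }
})

test_that("a proportional two-area split divides expected counts pro rata", {
  s <- collapse_strata(table1_fixture())
  split <- rbind(0.6 * s$population, 0.4 * s$population)
  E <- expected_counts(split, s$cases / s$population)
  expect_equal(E, c(214.8, 143.2), tolerance = 1e-9)
})

test_that("degenerate expected-count inputs are handled", {
  prev <- c(0.001, 0.002)
  expect_equal(expected_counts(matrix(0, 1, 2), prev), 0)
  expect_error(expected_counts(matrix(1, 1, 3), prev), "missing stratum")
})

test_that("prevalence rate ratios behave as ratios", {
  y <- c(4, 0, 9)
  expect_equal(prevalence_rate_ratio(y, y + c(0, 2, 0)), c(1, 0, 1))
  E <- c(2, 3, 4)
  # invariance under uniform integer scaling of counts and populations:
  # PRR uses internally standardized E, which scales with the data
  expect_equal(prevalence_rate_ratio(3 * y, 3 * E),
               prevalence_rate_ratio(y, E))
  expect_warning(prevalence_rate_ratio(c(1, 0), c(0, 1)), "zero expected")
})

test_that("composite indices are sums of Z-scores with known variance", {
  a <- c(1, 2, 3, 4, 5, 8)
  idx <- composite_index(a, 10 * a + 3)   # perfectly correlated components
  expect_lt(abs(mean(idx)), 1e-10)
  expect_equal(sqrt(mean(idx^2)), 2, tolerance = 1e-10)
  # perfectly anticorrelated components cancel
  expect_equal(max(abs(composite_index(a, -a))), 0, tolerance = 1e-12)
  # independent components add variances: SD ~ sqrt(2)
  set.seed(8)
  idx2 <- composite_index(rnorm(10000), rnorm(10000))
  expect_equal(sqrt(mean(idx2^2)), sqrt(2), tolerance = 0.05)
  expect_error(composite_index(rep(1, 5), 1:5), "constant")
})

test_that("adjustment design drops the reference stratum and logs the offset", {
  pop <- matrix(c(100, 200, 150, 250, 300), 1,
                dimnames = list(NULL, c("18-24", "F25-39", "M25-39",
                                        "40-54", "55+")))
  adj <- adjustment_design(pop)
  expect_equal(unlist(adj[1, 1:4], use.names = FALSE),
               c(100, 200, 150, 250) / 1000)
  expect_equal(adj$offset, log(1000))
  # everyone in the reference band: all four proportions zero
  pop2 <- matrix(c(0, 0, 0, 0, 1000), 1)
  colnames(pop2) <- colnames(pop)
  expect_equal(unlist(adjustment_design(pop2)[1, 1:4], use.names = FALSE),
               rep(0, 4))
})

test_that("area datasets carry consistent derived columns", {
  ds <- synthetic_area_data(seed = 21)
  expect_equal(ds$offset, log(ds$n))
  expect_equal(ds$prr, ds$y / ds$E)
  expect_true(all(ds$E > 0))
  p5 <- as.matrix(ds[, c("p_18_24", "p_f25_39", "p_m25_39", "p_40_54")])
  expect_true(all(rowSums(p5) <= 1 + 1e-12))
})

test_that("area data CSV round-trips and preserves the identity", {
  ds <- synthetic_area_data(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_area_data(ds, f)
  ds2 <- read_area_data(f)
  expect_equal(ds2$y, ds$y)
  expect_equal(ds2$n, ds$n)
  expect_lt(abs(sum(ds2$E) - sum(ds2$y)), 1e-9)
  unlink(f)
})
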