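# Shared fixtures and scaled-down MCMC settings for the test suite.

# short chains for unit tests; longer ones where a check needs them
quick_mcmc <- function(...) mcmc_control(n_burnin = 2000, n_sample = 10000,
                                         thin = 5, ...)

# a small, fully spelled-out 3-area toy: path graph, printed data
toy3 <- function() {
  list(y = c(2, 5, 3),
       offset = log(c(100, 120, 90)),
       W = matrix(c(0, 1, 0,
                    1, 0, 1,
                    0, 1, 0), 3, 3, byrow = TRUE))
}

# minimal object accepted by smoothed_rr(): posterior fitted samples only
fake_carfit <- function(fitted_samples, E = NULL) {
  structure(list(fitted_samples = fitted_samples, E = E,
                 n = ncol(fitted_samples)),
            class = "carfit")
}

# dense grid integration of the exact posterior of an intercept-only
# Poisson model with offset and N(0, v) prior: the brute-force oracle
# for MCMC moment checks
grid_posterior_mean <- function(y, offset, v = 1e5, lo = -8, hi = 0,
                                m = 8001) {
  g <- seq(lo, hi, length.out = m)
  lp <- vapply(g, function(b) {
    sum(y * (offset + b) - exp(offset + b)) + stats::dnorm(b, 0, sqrt(v),
                                                           log = TRUE)
  }, 0)
  w <- exp(lp - max(lp))
  sum(g * w) / sum(w)
}

# Monte-Carlo standard error of a chain mean, autocorrelation-robust
# (spectral density at zero over chain length)
mcse <- function(chain) {
  v <- stats::var(chain)
  fit <- tryCatch(stats::ar(chain, aic = TRUE, order.max = 30),
                  error = function(e) NULL)
  s0 <- if (is.null(fit) || length(fit$ar) == 0) v else
    fit$var.pred / (1 - sum(fit$ar))^2
  sqrt(s0 / length(chain))
}
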