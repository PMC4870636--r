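# Bayesian disease mapping: Poisson likelihood with CAR random effects,
# fit by Metropolis-within-Gibbs MCMC (compiled sampler in src/).

#' Prior settings for CAR disease-mapping models
#'
#' Weakly informative defaults: flat-ish Gaussian regression priors and
#' inverse-gamma variance priors; a uniform prior on the Leroux mixing
#' parameter.
#'
#' @param v_beta prior variance of each regression coefficient,
#'   \code{beta_j ~ N(0, v_beta)}.
#' @param tau2_shape,tau2_rate inverse-gamma prior on the structured
#'   variance \code{tau2}.
#' @param sigma2_shape,sigma2_rate inverse-gamma prior on the
#'   unstructured variance \code{sigma2}.
#' @return A list of class \code{"car_prior"}.
#' @export
car_prior <- function(v_beta = 1e5, tau2_shape = 1, tau2_rate = 0.01,
                      sigma2_shape = 1, sigma2_rate = 0.01) {
  stopifnot(v_beta > 0, tau2_shape > 0, tau2_rate > 0,
            sigma2_shape > 0, sigma2_rate > 0)
  structure(list(v_beta = v_beta, tau2_shape = tau2_shape,
                 tau2_rate = tau2_rate, sigma2_shape = sigma2_shape,
                 sigma2_rate = sigma2_rate), class = "car_prior")
}

#' MCMC run-length and tuning settings
#'
#' Defaults are headline-run sizes (20 000 burn-in, 100 000 post-burn-in
#' sweeps thinned by 10, so 10 000 retained draws); scale down for quick
#' exploration. Proposal scales are tuned adaptively during burn-in only
#' (toward acceptance rates in 0.2-0.6) and frozen afterwards so the
#' retained chain has a fixed transition kernel.
#'
#' @param n_burnin burn-in sweeps (discarded).
#' @param n_sample post-burn-in sweeps.
#' @param thin keep every \code{thin}-th post-burn-in sweep.
#' @param fix_tau2,fix_sigma2,fix_rho optional values at which to hold a
#'   variance component or the Leroux mixing parameter fixed (degenerate
#'   prior); mainly for calibration and limit checks.
#' @return A list of class \code{"mcmc_control"}.
#' @export
mcmc_control <- function(n_burnin = 20000, n_sample = 100000, thin = 10,
                         fix_tau2 = NULL, fix_sigma2 = NULL,
                         fix_rho = NULL) {
  stopifnot(n_burnin >= 0, n_sample >= thin, thin >= 1)
  n_save <- n_sample %/% thin
  structure(list(n_burnin = as.integer(n_burnin),
                 n_sample = as.integer(n_save * thin),
                 thin = as.integer(thin), n_save = as.integer(n_save),
                 fix_tau2 = fix_tau2, fix_sigma2 = fix_sigma2,
                 fix_rho = fix_rho),
            class = "mcmc_control")
}

#' CAR prior precision matrix
#'
#' Returns the precision matrix of the spatial random-effect prior for a
#' given structure: identity for the independent model, \code{D - W} for
#' the intrinsic autoregressive model (singular; used with a sum-to-zero
#' constraint), and \code{rho (D - W) + (1 - rho) I} for the Leroux
#' model, which interpolates between the two. The BYM convolution is
#' returned as its two parts.
#'
#' @param structure one of \code{"ind"}, \code{"iar"}, \code{"bym"},
#'   \code{"leroux"}.
#' @param W adjacency matrix or \code{area_lattice}.
#' @param rho Leroux mixing parameter in \code{[0, 1]} (Leroux only).
#' @return A matrix, or for \code{"bym"} a list with elements
#'   \code{structured} and \code{unstructured}.
#' @export
car_precision <- function(structure = c("leroux", "ind", "iar", "bym"), W,
                          rho = NULL) {
  structure <- match.arg(structure)
  W <- as_W(W)
  n <- nrow(W)
  D <- diag(rowSums(W))
  switch(structure,
         ind = diag(n),
         iar = {
           if (!is_connected(W)) {
             warning("disconnected graph: intrinsic prior needs one ",
                     "sum-to-zero constraint per component")
           }
           D - W
         },
         bym = list(structured = D - W, unstructured = diag(n)),
         leroux = {
           if (is.null(rho) || rho < 0 || rho > 1) {
             stop("Leroux precision needs rho in [0, 1]")
           }
           rho * (D - W) + (1 - rho) * diag(n)
         })
}

structure_code <- function(structure) {
  match(structure, c("ind", "iar", "bym", "leroux")) - 1L
}

#' Fit a Bayesian CAR disease-mapping model by MCMC
#'
#' Fits \code{y_k ~ Poisson(exp(offset_k + x_k' beta + phi_k + theta_k))}
#' with one of four random-effect structures: \code{"ind"} (exchangeable
#' effects shrinking area risks toward the overall mean), \code{"iar"}
#' (intrinsic autoregressive: each area's risk borrows strength from its
#' neighbours), \code{"bym"} (convolution of both) or \code{"leroux"}
#' (single field with a mixing parameter \code{rho} spanning the
#' independent and intrinsic limits). Sampling is Metropolis-within-Gibbs:
#' random-walk Metropolis for \code{beta} and each random-effect site
#' (the Poisson likelihood is non-conjugate), conjugate inverse-gamma
#' Gibbs draws for the variances, and Metropolis for \code{rho} with the
#' exact log-determinant term evaluated through the precomputed
#' eigenvalues of \code{D - W}. Structured effects are recentred to sum
#' to zero every sweep for identifiability with the intercept.
#'
#' @param y per-area case counts.
#' @param X covariate matrix (no intercept column; one is added), or NULL.
#' @param offset log persons at risk per area.
#' @param W binary symmetric adjacency matrix or \code{area_lattice}.
#' @param structure random-effect structure (see Details).
#' @param prior a \code{\link{car_prior}}.
#' @param mcmc an \code{\link{mcmc_control}}.
#' @param E optional expected counts stored for relative-risk reporting.
#' @param seed optional integer seed; fixed seed gives identical chains.
#' @return An object of class \code{"carfit"} with retained chains
#'   (\code{$chains}: beta, tau2, sigma2, rho, deviance), per-area fitted
#'   samples and posterior means, \code{$dic}, \code{$p_d},
#'   \code{$geweke}, an effect table \code{$or_table} (posterior rate
#'   ratios with 95\% credible intervals), and acceptance rates.
#' @examples
#' ds <- synthetic_area_data(seed = 7)
#' fit <- fit_car(ds$y, ds[, "ECON", drop = FALSE], log(ds$n),
#'                attr(ds, "lattice"), structure = "leroux",
#'                mcmc = mcmc_control(1000, 2000, thin = 2), seed = 1)
#' fit$dic
#' @export
fit_car <- function(y, X = NULL, offset, W,
                    structure = c("leroux", "ind", "iar", "bym"),
                    prior = car_prior(), mcmc = mcmc_control(),
                    E = NULL, seed = NULL) {
  structure <- match.arg(structure)
  W <- as_W(W)
  n <- length(y)
  if (nrow(W) != n || length(offset) != n) stop("inputs are not aligned")
  if (any(y < 0) || any(!is.finite(offset))) {
    stop("y must be nonnegative and offset finite")
  }
  Xc <- build_design(X, n)
  Xd <- cbind("(Intercept)" = 1, Xc)
  if (qr(Xd)$rank < ncol(Xd)) stop("design matrix is rank deficient")

  d <- rowSums(W)
  if (structure %in% c("iar", "bym", "leroux") && any(d == 0)) {
    stop("isolated areas: every area needs at least one neighbour")
  }
  if (structure %in% c("iar", "bym") && !is_connected(W)) {
    warning("disconnected graph: intrinsic prior needs one constraint ",
            "per component; results use a single global recentring")
  }
  nb <- lapply(seq_len(n), function(k) which(W[k, ] == 1) - 1L)
  lambda <- if (structure == "leroux") {
    eigen(diag(d) - W, symmetric = TRUE, only.values = TRUE)$values
  } else numeric(n)

  # initialize beta at the frequentist estimate where available
  beta_init <- tryCatch({
    f <- suppressWarnings(stats::glm.fit(Xd, y, family = stats::poisson(),
                                         offset = offset))
    b <- f$coefficients
    b[!is.finite(b)] <- 0
    b
  }, error = function(e) {
    c(log(sum(y) / sum(exp(offset))), rep(0, ncol(Xd) - 1L))
  })
  if (!all(is.finite(beta_init))) stop("non-finite posterior at initialization")

  if (!is.null(seed)) set.seed(seed)
  raw <- car_mcmc_cpp(as.numeric(y), Xd, as.numeric(offset), nb,
                      as.numeric(d), structure_code(structure),
                      prior$v_beta, prior$tau2_shape, prior$tau2_rate,
                      prior$sigma2_shape, prior$sigma2_rate,
                      lambda, as.numeric(beta_init),
                      mcmc$n_burnin, mcmc$n_save, mcmc$thin,
                      !is.null(mcmc$fix_rho),
                      if (is.null(mcmc$fix_rho)) 0 else mcmc$fix_rho,
                      !is.null(mcmc$fix_tau2),
                      if (is.null(mcmc$fix_tau2)) 0 else mcmc$fix_tau2,
                      !is.null(mcmc$fix_sigma2),
                      if (is.null(mcmc$fix_sigma2)) 0 else mcmc$fix_sigma2)
  colnames(raw$beta) <- colnames(Xd)

  acc <- raw$acceptance
  acc_used <- acc[!is.na(acc)]
  if (any(acc_used < 0.05 | acc_used > 0.95)) {
    warning("acceptance rate outside (0.05, 0.95) after tuning: ",
            paste(sprintf("%s=%.2f", names(acc_used), acc_used),
                  collapse = ", "))
  }

  chains <- list(beta = raw$beta, deviance = raw$deviance)
  if (structure %in% c("iar", "bym", "leroux") && is.null(mcmc$fix_tau2)) {
    chains$tau2 <- raw$tau2
  }
  if (structure %in% c("ind", "bym") && is.null(mcmc$fix_sigma2)) {
    chains$sigma2 <- raw$sigma2
  }
  if (structure == "leroux" && is.null(mcmc$fix_rho)) chains$rho <- raw$rho

  # DIC: Dbar + pD with pD = Dbar - D(posterior mean of parameters);
  # the plug-in deviance uses the posterior mean linear predictor.
  dbar <- mean(raw$deviance)
  mu_hat <- exp(raw$eta_mean)
  d_hat <- -2 * sum(y * raw$eta_mean - mu_hat - lgamma(y + 1))
  p_d <- dbar - d_hat
  dic <- dbar + p_d

  scalars <- scalar_chains(chains)
  gz <- vapply(scalars, function(ch) {
    if (stats::var(ch) == 0) NA_real_ else geweke_z(ch)
  }, numeric(1))

  qs <- t(apply(raw$beta, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  est <- colMeans(raw$beta)
  or_table <- data.frame(term = colnames(raw$beta), estimate = est,
                         or = exp(est), ci_low = exp(qs[, 1]),
                         ci_high = exp(qs[, 3]), row.names = NULL)

  out <- list(structure = structure, chains = chains,
                 fitted_samples = raw$fitted_samples,
                 fitted = colMeans(raw$fitted_samples),
                 eta_mean = raw$eta_mean,
                 phi_mean = raw$phi_mean, theta_mean = raw$theta_mean,
                 coefficients = est, or_table = or_table,
                 dic = dic, p_d = p_d, dbar = dbar,
                 geweke = gz, acceptance = acc,
                 prior = prior, mcmc = mcmc, y = y, offset = offset,
                 E = E, n = n, seed = seed)
  class(out) <- "carfit"
  out
}

# flatten a chains list into named scalar chains (for diagnostics/export)
scalar_chains <- function(chains) {
  out <- list()
  for (nm in names(chains)) {
    x <- chains[[nm]]
    if (is.matrix(x)) {
      for (j in seq_len(ncol(x))) {
        out[[paste0(nm, ".", colnames(x)[j])]] <- x[, j]
      }
    } else out[[nm]] <- x
  }
  out
}

#' @export
print.carfit <- function(x, digits = 4, ...) {
  lab <- c(ind = "independent (exchangeable)", iar = "intrinsic CAR",
           bym = "BYM convolution", leroux = "Leroux CAR")[x$structure]
  cat("Bayesian disease-mapping model:", lab, "\n")
  cat(sprintf("DIC: %.2f  (pD = %.2f, Dbar = %.2f)\n", x$dic, x$p_d, x$dbar))
  cat("Posterior rate ratios:\n")
  print(x$or_table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.carfit <- function(object, ...) {
  x <- object
  out <- list(structure = x$structure, or_table = x$or_table,
              dic = x$dic, p_d = x$p_d,
              geweke = x$geweke, max_abs_geweke = max(abs(x$geweke), na.rm = TRUE),
              acceptance = x$acceptance,
              n_save = length(x$chains$deviance))
  class(out) <- "summary.carfit"
  out
}

#' @export
print.summary.carfit <- function(x, digits = 4, ...) {
  cat("CAR model (", x$structure, "), ", x$n_save, " retained draws\n",
      sep = "")
  cat(sprintf("DIC %.2f (pD %.2f); max |Geweke Z| = %.2f %s\n", x$dic,
              x$p_d, x$max_abs_geweke,
              if (x$max_abs_geweke < 1.96) "(converged at the 1.96 rule)"
              else "(convergence questionable)"))
  print(x$or_table, digits = digits, row.names = FALSE)
  cat("Acceptance rates:",
      paste(sprintf("%s=%.2f", names(x$acceptance),
                    x$acceptance)[!is.na(x$acceptance)], collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.carfit <- function(object, ...) object$coefficients

#' @export
fitted.carfit <- function(object, ...) object$fitted

#' @export
residuals.carfit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") r <- r / sqrt(object$fitted)
  r
}

#' @export
plot.carfit <- function(x, pars = NULL, ...) {
  sc <- scalar_chains(x$chains)
  if (is.null(pars)) pars <- utils::head(names(sc), 4L)
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (nm in pars) {
    graphics::plot(sc[[nm]], type = "l", ylab = nm, xlab = "")
  }
  invisible(x)
}

#' Posterior predictive draws from a fitted CAR model
#'
#' @param object a \code{carfit}.
#' @param nsim number of replicate count vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return matrix (\code{nsim} x areas) of Poisson draws, each row using
#'   one retained posterior sample of the area means.
#' @export
simulate.carfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$fitted_samples), nsim, replace = TRUE)
  t(vapply(idx, function(i)
    stats::rpois(object$n, object$fitted_samples[i, ]),
    numeric(object$n)))
}

#' Deviance information criterion of a fitted CAR model
#'
#' \code{DIC = Dbar + pD} with \code{pD = Dbar - D(posterior mean)};
#' smaller values indicate better fit penalized for effective complexity.
#'
#' @param fit a \code{carfit}.
#' @return named numeric vector \code{c(dic, p_d)}.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "carfit"))
  c(dic = fit$dic, p_d = fit$p_d)
}

# spectral density of a chain at frequency zero, via an AR fit
# (variance of the sample mean times chain length, autocorrelation-robust)
spectrum0_ar <- function(x) {
  v <- stats::var(x)
  if (v == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(30L, length(x) - 1L)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(v)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first \code{first_frac} of a chain
#' with the mean of the last \code{last_frac}, using
#' spectral-density-at-zero variance estimates so chain autocorrelation
#' is accounted for. |Z| below 1.96 is consistent with convergence.
#'
#' @param chain numeric vector of MCMC draws (length >= 100).
#' @param first_frac,last_frac segment fractions (defaults 0.1 and 0.5).
#' @return a single Z value.
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 100L) stop("chain too short for the Geweke diagnostic")
  if (stats::var(chain) == 0) stop("zero-variance chain")
  a <- chain[seq_len(floor(first_frac * n))]
  b <- chain[seq.int(n - floor(last_frac * n) + 1L, n)]
  sa <- spectrum0_ar(a)
  sb <- spectrum0_ar(b)
  (mean(a) - mean(b)) / sqrt(sa / length(a) + sb / length(b))
}

#' Smoothed relative risks, exceedance probabilities and hotspot flags
#'
#' For each area, divides the posterior samples of the fitted mean count
#' by the expected count to get smoothed relative-risk samples, then
#' computes the exceedance probability \code{Pr(RR > 1 | data)}. Areas
#' whose smoothed risk exceeds unity with probability above the cutoff
#' (default 0.75) are flagged as raised-risk hotspots.
#'
#' @param fit a \code{carfit}.
#' @param E expected counts (defaults to those stored in the fit).
#' @param cutoff exceedance-probability threshold for the hotspot flag.
#' @return data.frame of class \code{"hotspot_report"} with columns
#'   \code{area}, \code{rr_mean}, \code{exceedance}, \code{hotspot}.
#' @export
smoothed_rr <- function(fit, E = fit$E, cutoff = 0.75) {
  stopifnot(inherits(fit, "carfit"))
  if (is.null(E)) stop("expected counts E are required")
  if (any(E <= 0)) stop("E must be positive")
  rr <- sweep(fit$fitted_samples, 2, E, "/")
  exceed <- colMeans(rr > 1)
  out <- data.frame(area = seq_along(E), rr_mean = colMeans(rr),
                    exceedance = exceed, hotspot = exceed > cutoff)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("hotspot_report", "data.frame")
  out
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat("Hotspot report (exceedance cutoff ", attr(x, "cutoff"), "): ",
      sum(x$hotspot), " of ", nrow(x), " areas flagged\n", sep = "")
  NextMethod()
}
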