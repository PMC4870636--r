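# Synthetic lattice data with known generative parameters.
#
# The generator mirrors the model the analysis assumes: area counts
#   y_k ~ Poisson(exp(log n_k + x_k' beta + phi_k + theta_k))
# with phi a Leroux-CAR Gaussian field (spatial dependence rho, variance
# tau2, sum-to-zero), theta exchangeable Gaussian noise (variance sigma2),
# and populations emulating ~2000-resident census micro-neighbourhoods.

# Adjustment strata: the four age-bands with 25-39 split by gender
# (the only band where prevalence differs by gender).
strata_names <- function() c("18-24", "F25-39", "M25-39", "40-54", "55+")

# Catchment stratum shares and per-stratum relative risks, both taken from
# the packaged catchment aggregates (see table1_fixture), used as generator
# defaults so synthetic areas have a realistic demographic mix.
default_strata_shares <- function() {
  s <- collapse_strata(table1_fixture())
  s$population / sum(s$population)
}

default_strata_rr <- function() {
  s <- collapse_strata(table1_fixture())
  prev <- s$cases / s$population
  prev / (sum(s$cases) / sum(s$population))
}

#' Parameters of the generative model for synthetic lattice data
#'
#' Collects the quantities the analysis later tries to recover: covariate
#' log-rate-ratios per SD, the Leroux spatial-dependence parameter, and the
#' structured / unstructured random-effect variances.
#'
#' @param beta numeric vector of covariate log-rate-ratios (per SD of each
#'   covariate); excludes the intercept, which is \code{log(baseline_prevalence)}.
#' @param rho spatial dependence in \code{[0, 1]}: 0 = independent effects,
#'   1 = intrinsic autoregressive.
#' @param tau2 variance of the spatially structured effect (>= 0).
#' @param sigma2 variance of the exchangeable (unstructured) effect (>= 0).
#' @param baseline_prevalence overall prevalence in (0, 1); the default is
#'   the catchment crude prevalence 358 / 109397.
#' @return A list of class \code{"generative_truth"}.
#' @export
generative_truth <- function(beta = c(ECON = 0.12, MIG = 0, FRAG = 0),
                             rho = 0.8, tau2 = 0.3, sigma2 = 0,
                             baseline_prevalence = 358 / 109397) {
  stopifnot(is.numeric(beta), rho >= 0, rho <= 1, tau2 >= 0, sigma2 >= 0,
            baseline_prevalence > 0, baseline_prevalence < 1)
  structure(list(beta = beta, rho = rho, tau2 = tau2, sigma2 = sigma2,
                 baseline_prevalence = baseline_prevalence),
            class = "generative_truth")
}

#' Simulate stratified area populations
#'
#' Draws per-area population totals from a lognormal distribution with the
#' requested mean and standard deviation (moment-matched, then rounded to
#' integers >= 1), and allocates each total across the five adjustment
#' strata by a Dirichlet-multinomial.
#'
#' @param lattice an \code{\link{grid_lattice}} object (or anything with
#'   \code{$n}).
#' @param mean_pop,sd_pop mean and SD of the per-area adult population;
#'   defaults 2064 and 705 emulate ~2000-resident census units.
#' @param strata_alpha Dirichlet concentration vector (length 5) for the
#'   stratum shares; the default centres on the catchment stratum mix with
#'   moderate between-area variability.
#' @param seed optional integer seed.
#' @return Object of class \code{"strat_pop"}: list with \code{strata}
#'   (n x 5 integer matrix), \code{n_total} (row sums) and \code{area_id}.
#' @export
simulate_population <- function(lattice, mean_pop = 2064, sd_pop = 705,
                                strata_alpha = 60 * default_strata_shares(),
                                seed = NULL) {
  if (mean_pop <= 0) stop("mean_pop must be positive")
  if (sd_pop < 0) stop("sd_pop must be nonnegative")
  if (length(strata_alpha) != 5L || any(strata_alpha <= 0)) {
    stop("strata_alpha must be 5 positive concentrations")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- lattice$n

  if (sd_pop == 0) {
    totals <- rep(max(1L, round(mean_pop)), n)
  } else {
    # lognormal matched to (mean, sd)
    s2 <- log(1 + sd_pop^2 / mean_pop^2)
    mu <- log(mean_pop) - s2 / 2
    totals <- pmax(1L, as.integer(round(exp(stats::rnorm(n, mu, sqrt(s2))))))
  }

  strata <- matrix(0L, n, 5L, dimnames = list(NULL, strata_names()))
  for (k in seq_len(n)) {
    g <- stats::rgamma(5L, shape = strata_alpha)
    p <- g / sum(g)
    strata[k, ] <- as.integer(stats::rmultinom(1L, totals[k], p))
  }
  structure(list(strata = strata, n_total = rowSums(strata),
                 area_id = lattice$area_id),
            class = "strat_pop")
}

#' @export
print.strat_pop <- function(x, ...) {
  cat("Stratified population:", length(x$n_total), "areas, total",
      sum(x$n_total), "persons at risk\n")
  cat("Per-area totals: mean", round(mean(x$n_total), 1),
      "sd", round(stats::sd(x$n_total), 1), "\n")
  invisible(x)
}

# Sample one draw of a zero-mean Leroux CAR field on adjacency W:
# precision tau2^-1 * (rho (D - W) + (1 - rho) I), recentred to sum to zero.
# At rho = 1 (intrinsic limit) the null direction is dropped.
r_car_field <- function(W, rho, tau2) {
  n <- nrow(W)
  if (tau2 == 0) return(numeric(n))
  eg <- eigen(diag(rowSums(W)) - W, symmetric = TRUE)
  prec <- rho * pmax(eg$values, 0) + (1 - rho)
  z <- stats::rnorm(n)
  z[prec < 1e-10] <- 0
  prec[prec < 1e-10] <- 1
  phi <- sqrt(tau2) * as.vector(eg$vectors %*% (z / sqrt(prec)))
  phi - mean(phi)
}

#' Simulate spatially smooth ecological covariates
#'
#' Generates covariate columns (economic deprivation, migrant density,
#' social fragmentation analogues) from a Leroux CAR Gaussian field so they
#' carry the spatial smoothness real census indices exhibit, then
#' standardizes each column to mean 0, SD 1 across areas (the Z-score
#' convention of the composite indices; population SD, i.e. divisor n).
#'
#' @param lattice an \code{area_lattice}.
#' @param spatial_corr Leroux dependence parameter in \code{[0, 1)}.
#' @param names column names; default the three ecological indices.
#' @param seed optional integer seed.
#' @return A numeric matrix with one standardized column per covariate.
#' @export
simulate_covariates <- function(lattice, spatial_corr = 0.8,
                                names = c("ECON", "MIG", "FRAG"),
                                seed = NULL) {
  if (spatial_corr < 0 || spatial_corr >= 1) {
    stop("spatial_corr must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- sapply(names, function(nm) {
    x <- r_car_field(lattice$W, spatial_corr, 1)
    zscore(x)
  })
  rownames(X) <- lattice$area_id
  X
}

#' Simulate area case counts from the generative model
#'
#' Draws \code{y_k ~ Poisson(exp(log n_k + x_k' beta + phi_k + theta_k))}
#' with \code{phi} a sum-to-zero Leroux CAR field at \code{(rho, tau2)} and
#' \code{theta} iid \code{N(0, sigma2)}. Cases within each area are then
#' allocated to the five adjustment strata in proportion to stratum
#' population times a stratum relative risk, so the indirect
#' standardization machinery downstream sees realistic age/gender
#' structure.
#'
#' @param truth a \code{\link{generative_truth}}.
#' @param pop a \code{\link{simulate_population}} result.
#' @param X covariate matrix (areas x covariates), columns matching
#'   \code{truth$beta}.
#' @param lattice the \code{area_lattice} the field lives on.
#' @param strata_rr per-stratum relative risks used only to allocate cases
#'   within areas; defaults to the catchment pattern.
#' @param seed optional integer seed.
#' @return Object of class \code{"case_counts"}: list with \code{y},
#'   \code{strata_cases} (n x 5), \code{phi}, \code{theta}, \code{eta}.
#' @export
simulate_counts <- function(truth, pop, X, lattice,
                            strata_rr = default_strata_rr(), seed = NULL) {
  stopifnot(inherits(truth, "generative_truth"))
  n <- length(pop$n_total)
  if (nrow(X) != n || lattice$n != n) stop("dimensions of pop, X, lattice disagree")
  if (ncol(X) != length(truth$beta)) {
    stop("ncol(X) must match length(truth$beta)")
  }
  if (!is.null(seed)) set.seed(seed)

  phi <- r_car_field(lattice$W, truth$rho, truth$tau2)
  theta <- if (truth$sigma2 > 0) stats::rnorm(n, 0, sqrt(truth$sigma2)) else numeric(n)
  eta <- log(pop$n_total) + log(truth$baseline_prevalence) +
    as.vector(X %*% truth$beta) + phi + theta
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  y <- stats::rpois(n, exp(eta))

  strata_cases <- matrix(0L, n, 5L, dimnames = list(NULL, strata_names()))
  for (k in seq_len(n)) {
    if (y[k] > 0L) {
      w <- pop$strata[k, ] * strata_rr
      if (sum(w) <= 0) w <- rep(1, 5)
      strata_cases[k, ] <- as.integer(stats::rmultinom(1L, y[k], w / sum(w)))
    }
  }
  structure(list(y = y, strata_cases = strata_cases, phi = phi,
                 theta = theta, eta = eta),
            class = "case_counts")
}

#' Generate a complete synthetic area dataset
#'
#' Convenience wrapper chaining \code{\link{simulate_population}},
#' \code{\link{simulate_covariates}} and \code{\link{simulate_counts}},
#' then assembling an analysis-ready \code{\link{area_dataset}} with
#' internally standardized expected counts. Defaults reproduce the study
#' conditions the package is designed around: a 7 x 8 rook lattice (56
#' areas, close to the 53 administrative units of the motivating
#' catchment), populations ~2064 +/- 705, crude prevalence 358 / 109397.
#'
#' @param lattice an \code{area_lattice}; default 7 x 8 rook grid.
#' @param truth a \code{\link{generative_truth}}.
#' @param mean_pop,sd_pop population moments, see
#'   \code{\link{simulate_population}}.
#' @param covariate_corr spatial smoothness of covariates.
#' @param seed optional integer seed controlling the whole draw.
#' @return An \code{\link{area_dataset}} with attribute \code{"truth"} and
#'   extra columns for the latent \code{phi}, \code{theta}.
#' @export
synthetic_area_data <- function(lattice = grid_lattice(7, 8),
                                truth = generative_truth(),
                                mean_pop = 2064, sd_pop = 705,
                                covariate_corr = 0.8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(truth$beta))) {
    names(truth$beta) <- paste0("X", seq_along(truth$beta))
  }
  pop <- simulate_population(lattice, mean_pop, sd_pop)
  X <- simulate_covariates(lattice, covariate_corr,
                           names = names(truth$beta))
  cc <- simulate_counts(truth, pop, X, lattice)
  ds <- area_dataset(y = cc$y, pop = pop, X = X,
                     strata_cases = cc$strata_cases, lattice = lattice)
  attr(ds, "truth") <- truth
  attr(ds, "phi") <- cc$phi
  attr(ds, "theta") <- cc$theta
  ds
}

#' Catchment aggregate fixture: cases and populations by age-band and gender
#'
#' Returns the packaged catchment-level table of treated-psychosis case
#' counts and adult populations at risk for the 4 age-bands x 2 genders,
#' as published for the Creteil / Maisons-Alfort catchment (2014-2015
#' censuses of treated non-affective psychotic disorder; 2010 population
#' census denominators).
#'
#' @return A data.frame with columns \code{age_band}, \code{gender},
#'   \code{cases}, \code{population}.
#' @examples
#' t1 <- table1_fixture()
#' sum(t1$cases)   # 358 included cases
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "catchment_table1.csv", package = "carprev",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Catchment bookkeeping constants
#'
#' Published catchment-level counts used by the worked examples: cases
#' identified and excluded, number of areal units, and the adult
#' populations of the two cities.
#'
#' @return A named list.
#' @export
catchment_meta <- function() {
  list(cases_identified = 462L, cases_excluded = 104L, n_areas = 53L,
       pop_creteil = 66681L, pop_maisons_alfort = 42716L)
}

#' Collapse the age-band x gender table to the five adjustment strata
#'
#' The 25-39 band is kept split by gender (prevalence differs between men
#' and women there); the other bands are pooled.
#'
#' @param t1 a data.frame as returned by \code{\link{table1_fixture}}.
#' @return data.frame with columns \code{stratum}, \code{cases},
#'   \code{population}, rows ordered as \code{strata_names()}.
#' @export
collapse_strata <- function(t1) {
  lab <- ifelse(t1$age_band == "25-39",
                paste0(substr(t1$gender, 1, 1), "25-39"),
                t1$age_band)
  agg <- stats::aggregate(cbind(cases, population) ~ lab, data = cbind(t1, lab),
                          FUN = sum)
  agg <- agg[match(strata_names(), agg$lab), ]
  data.frame(stratum = strata_names(), cases = agg$cases,
             population = agg$population, row.names = NULL)
}
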