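# Indirect standardization and ecological index construction.

# Z-score with population SD (divisor n), the convention used for every
# standardized column in this package.
zscore <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to standardize")
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

#' Stratum-specific prevalences with Wilson confidence intervals
#'
#' Prevalence per stratum as a percentage, \code{100 * cases / population},
#' with a Wilson score 95\% interval.
#'
#' @param cases,population aligned nonnegative vectors; \code{population}
#'   must be strictly positive.
#' @param conf_level confidence level for the Wilson interval.
#' @return data.frame with columns \code{cases}, \code{population},
#'   \code{prevalence} (percent), \code{ci_low}, \code{ci_high} (percent).
#' @examples
#' # catchment-wide prevalences by adjustment stratum
#' stratum_prevalence(collapse_strata(table1_fixture())$cases,
#'                    collapse_strata(table1_fixture())$population)
#' @export
stratum_prevalence <- function(cases, population, conf_level = 0.95) {
  if (length(cases) != length(population)) stop("cases/population lengths differ")
  bad <- which(population <= 0)
  if (length(bad)) {
    stop("zero or negative population in stratum ", paste(bad, collapse = ", "))
  }
  p <- cases / population
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / population
  centre <- (p + z^2 / (2 * population)) / denom
  half <- z * sqrt(p * (1 - p) / population + z^2 / (4 * population^2)) / denom
  out <- data.frame(cases = cases, population = population,
                    prevalence = 100 * p,
                    ci_low = 100 * pmax(0, centre - half),
                    ci_high = 100 * pmin(1, centre + half))
  if (!is.null(names(cases))) rownames(out) <- names(cases)
  out
}

#' Indirectly standardized expected counts
#'
#' Applies whole-population stratum prevalences to each area's stratum
#' denominators: \code{E_k = sum_s pop[k, s] * prev_s}. When the
#' prevalences are computed from the same dataset (internal
#' standardization) the expected counts reproduce the observed total,
#' \code{sum(E) == sum(y)}.
#'
#' @param pop a \code{\link{simulate_population}}-style object or an
#'   areas x strata population matrix.
#' @param overall_prev per-stratum prevalence as a proportion (not
#'   percent), aligned with the population columns.
#' @return Numeric vector of expected counts, one per area.
#' @export
expected_counts <- function(pop, overall_prev) {
  strata <- if (inherits(pop, "strat_pop")) pop$strata else as.matrix(pop)
  if (ncol(strata) != length(overall_prev)) {
    stop("missing stratum: population has ", ncol(strata),
         " strata but prevalence has ", length(overall_prev))
  }
  if (any(!is.finite(overall_prev)) || any(overall_prev < 0)) {
    stop("stratum prevalences must be finite and nonnegative")
  }
  as.vector(strata %*% overall_prev)
}

#' Prevalence rate ratios
#'
#' Ratio of observed to expected counts per area, \code{y_k / E_k} — the
#' standardized-morbidity-ratio analogue for prevalence data. Areas with
#' \code{E = 0} and \code{y > 0} are flagged infinite.
#'
#' @param y observed counts.
#' @param E expected counts from \code{\link{expected_counts}}.
#' @return Numeric vector of rate ratios (0 where \code{y = E = 0}).
#' @export
prevalence_rate_ratio <- function(y, E) {
  if (length(y) != length(E)) stop("y/E lengths differ")
  prr <- ifelse(E > 0, y / E, ifelse(y > 0, Inf, 0))
  if (any(is.infinite(prr))) {
    warning(sum(is.infinite(prr)), " area(s) with cases but zero expected count")
  }
  prr
}

#' Composite ecological index from two component proportions
#'
#' Standardizes each component across areas to a Z-score (mean 0, SD 1,
#' population SD) and sums the two, following the usual construction of
#' deprivation / migrant-density / fragmentation indices from paired
#' census proportions.
#'
#' @param prop_a,prop_b per-area component values (e.g. percentage
#'   unemployed and proportion of car-free households).
#' @param name optional index label.
#' @return Numeric vector \code{z(prop_a) + z(prop_b)} with attribute
#'   \code{"name"}; mean 0, SD in (0, 2].
#' @export
composite_index <- function(prop_a, prop_b, name = NULL) {
  if (length(prop_a) != length(prop_b)) stop("component lengths differ")
  if (length(prop_a) < 2L) stop("need at least 2 areas")
  v <- zscore(prop_a) + zscore(prop_b)
  attr(v, "name") <- name
  v
}

#' Confounder-adjustment design columns and offset
#'
#' Per-area proportions of residents at risk in the four non-reference
#' adjustment strata (18-24, females 25-39, males 25-39, 40-54; the 55+
#' band is the reference and omitted) plus the log-population offset.
#'
#' @param pop a \code{strat_pop} or areas x 5 stratum population matrix
#'   with columns ordered as \code{strata_names()}.
#' @return data.frame with columns \code{p_18_24}, \code{p_f25_39},
#'   \code{p_m25_39}, \code{p_40_54} and \code{offset} (= log n_k).
#' @export
adjustment_design <- function(pop) {
  strata <- if (inherits(pop, "strat_pop")) pop$strata else as.matrix(pop)
  n_k <- rowSums(strata)
  if (any(n_k <= 0)) stop("every area must have positive population")
  P <- strata[, 1:4, drop = FALSE] / n_k
  out <- data.frame(p_18_24 = P[, 1], p_f25_39 = P[, 2],
                    p_m25_39 = P[, 3], p_40_54 = P[, 4],
                    offset = log(n_k))
  rownames(out) <- NULL
  out
}

#' Assemble an analysis-ready area dataset
#'
#' Bundles observed counts, stratified populations, covariates,
#' internally standardized expected counts, prevalence rate ratios and the
#' adjustment design into one data.frame (one row per area). Expected
#' counts use the dataset's own overall stratum prevalences, so
#' \code{sum(E) == sum(y)} by construction.
#'
#' @param y per-area case counts.
#' @param pop a \code{strat_pop} or areas x 5 stratum population matrix.
#' @param X covariate matrix (may be NULL).
#' @param strata_cases optional areas x 5 matrix of per-stratum case
#'   counts; defaults to allocating each area's cases proportionally to
#'   its stratum populations (equivalent to single-stratum
#'   standardization).
#' @param lattice optional \code{area_lattice} stored as an attribute.
#' @return data.frame of class \code{"area_dataset"} with columns
#'   \code{area_id}, \code{y}, \code{n}, stratum populations, adjustment
#'   proportions, \code{offset}, covariates, \code{E}, \code{prr}.
#' @export
area_dataset <- function(y, pop, X = NULL, strata_cases = NULL,
                         lattice = NULL) {
  strata <- if (inherits(pop, "strat_pop")) pop$strata else as.matrix(pop)
  n <- nrow(strata)
  if (length(y) != n) stop("y and population dimensions disagree")
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative integers")
  n_k <- rowSums(strata)

  if (is.null(strata_cases)) {
    # no age/gender detail: spread cases like the population, which makes
    # the overall stratum prevalences all equal to the crude prevalence
    stratum_cases_tot <- colSums(strata) * sum(y) / sum(n_k)
  } else {
    if (!all(rowSums(strata_cases) == y)) {
      stop("strata_cases rows must sum to y")
    }
    stratum_cases_tot <- colSums(strata_cases)
  }
  overall_prev <- stratum_cases_tot / colSums(strata)
  E <- expected_counts(strata, overall_prev)

  adj <- adjustment_design(strata)
  ds <- data.frame(area_id = if (!is.null(lattice)) lattice$area_id else
                     sprintf("A%03d", seq_len(n)),
                   y = as.integer(y), n = n_k,
                   strata, adj, check.names = FALSE)
  if (!is.null(X)) ds <- cbind(ds, X)
  ds$E <- E
  ds$prr <- prevalence_rate_ratio(y, E)
  attr(ds, "covariates") <- colnames(X)
  attr(ds, "lattice") <- lattice
  attr(ds, "stratum_prevalence") <- overall_prev
  class(ds) <- c("area_dataset", "data.frame")
  ds
}

#' @export
print.area_dataset <- function(x, ...) {
  cat("Area dataset:", nrow(x), "areas,", sum(x$y), "cases,",
      sum(x$n), "persons at risk\n")
  cat("Crude prevalence:", format(100 * sum(x$y) / sum(x$n), digits = 3),
      "% ; covariates:",
      paste(attr(x, "covariates"), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more areas\n")
  invisible(x)
}
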