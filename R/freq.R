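# Frequentist count models with log-population offsets, plus the two
# validity diagnostics that gate the move to spatial models: Dean's
# overdispersion score test and Moran's I residual autocorrelation test.

build_design <- function(X, n) {
  if (is.null(X)) {
    matrix(numeric(0), n, 0)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    X
  }
}

glm_fit_record <- function(fit, family, theta = NULL) {
  cf <- summary(fit)$coefficients
  est <- cf[, 1]
  se <- cf[, 2]
  z <- stats::qnorm(0.975)
  or_table <- data.frame(term = rownames(cf), estimate = est, se = se,
                         or = exp(est),
                         ci_low = exp(est - z * se),
                         ci_high = exp(est + z * se),
                         p_value = cf[, 4], row.names = NULL)
  structure(list(family = family, fit = fit,
                 coefficients = stats::coef(fit), se = se,
                 theta = theta,
                 fitted = stats::fitted(fit),
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 or_table = or_table),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, digits = 4, ...) {
  cat("Log-linear", x$family, "model (offset rate model)\n")
  if (!is.null(x$theta)) {
    cat("Dispersion theta:", format(x$theta, digits = digits), "\n")
  }
  cat("AIC:", format(x$aic, digits = 6), "  logLik:",
      format(x$loglik, digits = 6), "\n\n")
  print(x$or_table, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.glm_fit <- function(object, ...) object$coefficients

#' @export
fitted.glm_fit <- function(object, ...) object$fitted

#' @export
residuals.glm_fit <- function(object, type = c("pearson", "deviance", "response"),
                              ...) {
  stats::residuals(object$fit, type = match.arg(type))
}

#' Fit a Poisson log-linear rate model
#'
#' Maximum-likelihood Poisson regression with log link and a
#' log-population offset, so coefficients are log rate ratios. Fitting is
#' by iteratively reweighted least squares via \code{stats::glm}.
#'
#' @param y per-area case counts.
#' @param X covariate matrix (no intercept column; one is always added),
#'   or NULL for an intercept-only model.
#' @param offset log persons at risk per area.
#' @return A \code{"glm_fit"} object: coefficients, SEs, fitted means,
#'   log-likelihood, AIC and a rate-ratio table \code{or_table}.
#' @examples
#' ds <- synthetic_area_data(seed = 1)
#' fit <- fit_poisson(ds$y, ds[, c("ECON", "MIG", "FRAG")], log(ds$n))
#' fit$or_table
#' @export
fit_poisson <- function(y, X = NULL, offset = rep(0, length(y))) {
  if (any(!is.finite(offset))) stop("offset must be finite")
  X <- build_design(X, length(y))
  df <- data.frame(y = y, X, check.names = TRUE)
  fit <- stats::glm(y ~ ., data = df, family = stats::poisson(),
                    offset = offset,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) stop("Poisson IRLS did not converge")
  if (any(is.na(stats::coef(fit)))) stop("design matrix is rank deficient")
  glm_fit_record(fit, "poisson")
}

#' Fit a negative binomial (NB2) rate model
#'
#' NB2 log-linear regression (variance \code{mu + mu^2 / theta}) with
#' offset, dispersion estimated by maximum likelihood via
#' \code{MASS::glm.nb}. The AIC counts theta as an estimated parameter.
#' Data that are effectively equidispersed (theta diverging) are reported
#' with a finite capped theta and flagged \code{equidispersed}.
#'
#' @inheritParams fit_poisson
#' @return A \code{"glm_fit"} object with element \code{theta}.
#' @export
fit_negbin <- function(y, X = NULL, offset = rep(0, length(y))) {
  if (any(!is.finite(offset))) stop("offset must be finite")
  X <- build_design(X, length(y))
  df <- data.frame(y = y, X, check.names = TRUE)
  off <- offset
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ . - off + offset(off),
                                  data = cbind(df, off = off),
                                  control = stats::glm.control(epsilon = 1e-10,
                                                               maxit = 200))),
    error = function(e) stop("negative binomial fit failed: ",
                             conditionMessage(e)))
  if (any(is.na(stats::coef(fit)))) stop("design matrix is rank deficient")
  rec <- glm_fit_record(fit, "negbin", theta = fit$theta)
  rec$equidispersed <- fit$theta > 1e5 || (!is.null(fit$th.warn))
  rec
}

#' Dean's score test for Poisson overdispersion
#'
#' Computes the score statistic
#' \deqn{P_B = \sum_k [(y_k - \hat\mu_k)^2 - y_k] / \sqrt{2 \sum_k \hat\mu_k^2}}
#' from a fitted Poisson model and compares it one-sided to N(0, 1):
#' values above 1.96 indicate overdispersion at the 5\% level, i.e. count
#' variance exceeding the mean, invalidating the Poisson assumption.
#'
#' @param fit a \code{"glm_fit"} from \code{\link{fit_poisson}} (or a
#'   Poisson \code{glm}).
#' @param alpha test level for the reported decision.
#' @return A list of class \code{"carprev_diag"}: \code{statistic},
#'   \code{p_value}, \code{decision}, \code{variant = "P_B"}.
#' @export
dean_test <- function(fit, alpha = 0.05) {
  if (inherits(fit, "glm_fit")) {
    if (fit$family != "poisson") stop("Dean's test applies to a Poisson fit")
    y <- fit$fit$y; mu <- fit$fitted
  } else {
    y <- fit$y; mu <- stats::fitted(fit)
  }
  if (length(y) < 10L) {
    warning("fewer than 10 areas: normal approximation is unreliable")
  }
  stat <- sum((y - mu)^2 - y) / sqrt(2 * sum(mu^2))
  p <- stats::pnorm(stat, lower.tail = FALSE)
  structure(list(name = "dean", variant = "P_B", statistic = stat,
                 reference = "one-sided N(0,1)", p_value = p,
                 alpha = alpha,
                 decision = stat > stats::qnorm(1 - alpha)),
            class = "carprev_diag")
}

#' @export
print.carprev_diag <- function(x, ...) {
  lab <- switch(x$name, dean = "Dean's overdispersion test (P_B)",
                moran = "Moran's I spatial autocorrelation test", x$name)
  cat(lab, "\n statistic:", format(x$statistic, digits = 4),
      " p-value:", format(x$p_value, digits = 4),
      " reference:", x$reference, "\n decision at alpha =", x$alpha, ":",
      if (x$decision) "reject null" else "do not reject", "\n")
  invisible(x)
}

#' Moran's I test for spatial autocorrelation
#'
#' Computes \deqn{I = (n / S_0) \sum_i \sum_j w_{ij} z_i z_j / \sum_i z_i^2}
#' with \code{z} the centred input and \code{S_0} the total weight. The
#' null expectation is \code{-1/(n-1)}. The p-value comes either from the
#' normal approximation under the randomization assumption, or from a
#' Monte-Carlo permutation distribution.
#'
#' @param x residual vector (typically Pearson residuals of the best
#'   frequentist fit).
#' @param W binary symmetric adjacency matrix or \code{area_lattice}.
#' @param method \code{"normal"} or \code{"permutation"}.
#' @param nperm number of permutations (permutation method).
#' @param alternative \code{"greater"} (positive autocorrelation, the
#'   default directional alternative), \code{"less"} or \code{"two.sided"}.
#' @param alpha level for the reported decision.
#' @return A \code{"carprev_diag"} with \code{statistic} (I),
#'   \code{expectation}, \code{variance} (normal method), \code{p_value},
#'   \code{decision}.
#' @export
moran_test <- function(x, W, method = c("normal", "permutation"),
                       nperm = 999, alternative = c("greater", "two.sided",
                                                    "less"),
                       alpha = 0.05) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  W <- as_W(W)
  n <- length(x)
  if (nrow(W) != n) stop("length(x) must match nrow(W)")
  z <- x - mean(x)
  if (all(z == 0)) stop("constant input: Moran's I undefined")
  S0 <- sum(W)
  I_obs <- (n / S0) * as.numeric(z %*% W %*% z) / sum(z^2)
  EI <- -1 / (n - 1)

  if (method == "normal") {
    # randomization-assumption variance (kurtosis-adjusted)
    S1 <- 2 * S0                      # binary symmetric weights
    d <- rowSums(W)
    S2 <- sum((2 * d)^2)
    b2 <- n * sum(z^4) / sum(z^2)^2
    varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
               b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
    zstat <- (I_obs - EI) / sqrt(varI)
    p <- switch(alternative,
                greater = stats::pnorm(zstat, lower.tail = FALSE),
                less = stats::pnorm(zstat),
                two.sided = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE))
    ref <- "normal approximation (randomization)"
  } else {
    ed <- adjacency_edges(W)
    Iperm <- moran_perm_cpp(z, ed$area_i - 1L, ed$area_j - 1L, nperm)
    Iperm <- (n / S0) * Iperm / sum(z^2)
    p <- switch(alternative,
                greater = (1 + sum(Iperm >= I_obs)) / (nperm + 1),
                less = (1 + sum(Iperm <= I_obs)) / (nperm + 1),
                two.sided = (1 + sum(abs(Iperm - EI) >= abs(I_obs - EI))) /
                  (nperm + 1))
    varI <- stats::var(Iperm)
    ref <- sprintf("permutation (%d draws)", nperm)
  }
  structure(list(name = "moran", statistic = I_obs, expectation = EI,
                 variance = varI, reference = ref, p_value = p,
                 alternative = alternative, alpha = alpha,
                 decision = p < alpha),
            class = "carprev_diag")
}

#' Forward selection of explanatory variables by information criterion
#'
#' Starting from a confounders-only base model, fits the base plus each
#' remaining candidate in turn; the candidate with the lowest criterion is
#' added if it strictly improves on the current base (ties favour the
#' smaller model), and the procedure repeats until no candidate improves.
#'
#' @param y case counts.
#' @param X_confounders confounder matrix always included (may be NULL).
#' @param candidates named matrix/data.frame of candidate covariates.
#' @param offset log persons at risk.
#' @param fitter fitting function \code{function(y, X, offset)}; defaults
#'   to \code{\link{fit_poisson}}.
#' @param criterion function extracting the criterion from a fit
#'   (default AIC via \code{$aic}); smaller is better.
#' @return List of class \code{"forward_selection"}: \code{best} (fit),
#'   \code{selected} (character), \code{trace} (data.frame with one row
#'   per fitted model: round, variables, criterion, selected flag).
#' @export
forward_select <- function(y, X_confounders, candidates, offset,
                           fitter = fit_poisson,
                           criterion = function(f) f$aic) {
  candidates <- as.matrix(candidates)
  cand_names <- colnames(candidates)
  if (is.null(cand_names)) stop("candidates must be named")
  conf <- build_design(X_confounders, length(y))
  if (length(intersect(colnames(conf), cand_names))) {
    stop("candidates must be disjoint from confounders")
  }

  fit_with <- function(vars) {
    X <- cbind(conf, candidates[, vars, drop = FALSE])
    if (ncol(X) == 0) X <- NULL
    fitter(y, X, offset)
  }

  selected <- character(0)
  base_fit <- fit_with(selected)
  base_crit <- criterion(base_fit)
  trace <- data.frame(round = 0L, variables = "(base)",
                      criterion = base_crit, selected = TRUE)
  remaining <- cand_names
  round_i <- 0L
  repeat {
    if (!length(remaining)) break
    round_i <- round_i + 1L
    crits <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      fits[[i]] <- tryCatch(fit_with(c(selected, remaining[i])),
                            error = function(e) {
                              warning("candidate ", remaining[i],
                                      " failed to fit: ", conditionMessage(e))
                              NULL
                            })
      if (!is.null(fits[[i]])) crits[i] <- criterion(fits[[i]])
    }
    trace <- rbind(trace, data.frame(
      round = round_i,
      variables = paste(vapply(remaining, function(v)
        paste(c(selected, v), collapse = "+"), ""), sep = ""),
      criterion = crits, selected = FALSE))
    if (all(is.na(crits))) break
    best_i <- which.min(crits)
    if (crits[best_i] < base_crit) {   # strict improvement
      selected <- c(selected, remaining[best_i])
      base_fit <- fits[[best_i]]
      base_crit <- crits[best_i]
      trace$selected[nrow(trace) - length(remaining) + best_i] <- TRUE
      remaining <- remaining[-best_i]
    } else break
  }
  structure(list(best = base_fit, selected = selected, trace = trace,
                 criterion_value = base_crit),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("Forward selection:",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "no explanatory variable retained",
      "\nFinal criterion:", format(x$criterion_value, digits = 6), "\n\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}
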