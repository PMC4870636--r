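# End-to-end analysis pipeline: validity-gated escalation from Poisson
# regression to negative binomial to the Bayesian CAR sweep.

#' Run the full small-area prevalence analysis pipeline
#'
#' Implements the escalation logic of the analysis: start with the
#' simplest model and move to more complex ones only when validity tests
#' require it. Stages: (1) Poisson forward selection over the ecological
#' covariates, always adjusted for the demographic confounder
#' proportions; (2) Dean's overdispersion test on the best Poisson model
#' — if equidispersed the pipeline stops here; (3) negative binomial
#' forward selection; (4) Moran's I on the Pearson residuals of the best
#' frequentist model — if no autocorrelation (and \code{force_bayesian}
#' is FALSE) the pipeline stops; (5) the CAR sweep: forward selection by
#' DIC within each of the four random-effect structures; (6) comparison
#' of the best frequentist and best Bayesian fits by r-squared and RMSD;
#' (7) hotspot report from the best Bayesian model.
#'
#' @param data an \code{\link{area_dataset}} (its lattice attribute
#'   supplies the adjacency), or pass \code{W} explicitly.
#' @param candidates names of candidate explanatory columns in
#'   \code{data}; defaults to the dataset's covariate attribute.
#' @param W adjacency matrix or \code{area_lattice} (optional if stored
#'   in \code{data}).
#' @param adjust use the four demographic adjustment proportions as
#'   always-included confounders.
#' @param alpha level for both validity gates.
#' @param moran_method \code{"normal"} or \code{"permutation"}.
#' @param force_bayesian run the CAR sweep even if Moran's I is not
#'   significant.
#' @param prior,mcmc settings passed to \code{\link{fit_car}}; the
#'   default chain sizes are moderate (5000 burn-in, 2000 retained) since
#'   the sweep fits many models.
#' @param seed integer seed controlling every stochastic step.
#' @return list of class \code{"pipeline_result"}; see Details.
#' @export
run_pipeline <- function(data, candidates = attr(data, "covariates"),
                         W = attr(data, "lattice"), adjust = TRUE,
                         alpha = 0.05,
                         moran_method = c("normal", "permutation"),
                         force_bayesian = FALSE, prior = car_prior(),
                         mcmc = mcmc_control(5000, 20000, thin = 10),
                         seed = NULL) {
  moran_method <- match.arg(moran_method)
  if (is.null(W)) stop("an adjacency structure is required")
  W <- as_W(W)
  if (is.null(candidates) || !length(candidates)) {
    stop("no candidate explanatory variables")
  }
  if (!is.null(seed)) set.seed(seed)

  y <- data$y
  offset <- log(data$n)
  E <- data$E
  conf <- if (adjust) {
    as.matrix(data[, c("p_18_24", "p_f25_39", "p_m25_39", "p_40_54")])
  } else NULL
  cand <- as.matrix(data[, candidates, drop = FALSE])

  res <- list(stages = character(0), alpha = alpha, seed = seed)

  # stage 1: Poisson forward selection by AIC
  res$stages <- c(res$stages, "poisson")
  res$poisson <- forward_select(y, conf, cand, offset, fitter = fit_poisson)

  # stage 2: overdispersion gate
  res$stages <- c(res$stages, "dean")
  res$dean <- dean_test(res$poisson$best, alpha = alpha)
  if (!res$dean$decision) {
    res$best_freq <- res$poisson$best
    res$best_family <- "poisson"
    res$stopped_at <- "poisson"
    res$summary <- pipeline_summary(res, data)
    class(res) <- "pipeline_result"
    return(res)
  }

  # stage 3: negative binomial forward selection
  res$stages <- c(res$stages, "negbin")
  res$negbin <- forward_select(y, conf, cand, offset, fitter = fit_negbin)
  res$best_freq <- res$negbin$best
  res$best_family <- "negbin"

  # stage 4: residual autocorrelation gate
  res$stages <- c(res$stages, "moran")
  res$moran <- moran_test(residuals(res$best_freq, "pearson"), W,
                          method = moran_method, alpha = alpha)
  if (!res$moran$decision && !force_bayesian) {
    res$stopped_at <- "negbin"
    res$summary <- pipeline_summary(res, data)
    class(res) <- "pipeline_result"
    return(res)
  }

  # stage 5: CAR sweep — forward selection by DIC within each structure
  res$stages <- c(res$stages, "car_sweep")
  fit_counter <- 0L
  res$car <- list()
  for (st in c("ind", "iar", "bym", "leroux")) {
    car_fitter <- function(y, X, offset) {
      fit_counter <<- fit_counter + 1L
      fit_car(y, X, offset, W, structure = st, prior = prior, mcmc = mcmc,
              E = E,
              seed = if (is.null(seed)) NULL else seed + 1000L * fit_counter)
    }
    res$car[[st]] <- forward_select(y, conf, cand, offset,
                                    fitter = car_fitter,
                                    criterion = function(f) f$dic)
  }
  best_st <- names(res$car)[which.min(vapply(res$car, `[[`, 0,
                                             "criterion_value"))]
  res$best_bayes <- res$car[[best_st]]$best
  res$best_structure <- best_st
  res$stopped_at <- "car_sweep"

  # stage 6: cross-paradigm comparison
  res$stages <- c(res$stages, "compare")
  res$comparison <- data.frame(
    model = c(paste0("frequentist_", res$best_family),
              paste0("bayes_", best_st)),
    r2 = c(r_squared(y, fitted(res$best_freq)),
           r_squared(y, fitted(res$best_bayes))),
    rmsd = c(rmsd(y, fitted(res$best_freq)),
             rmsd(y, fitted(res$best_bayes))))

  # stage 7: hotspot report from the best Bayesian model
  res$stages <- c(res$stages, "hotspots")
  res$hotspots <- smoothed_rr(res$best_bayes, E)

  res$summary <- pipeline_summary(res, data)
  class(res) <- "pipeline_result"
  res
}

pipeline_summary <- function(res, data) {
  best_is_bayes <- !is.null(res$best_bayes)
  best <- if (best_is_bayes) res$best_bayes else res$best_freq
  list(
    n_areas = nrow(data), total_cases = sum(data$y),
    crude_prevalence_percent = 100 * sum(data$y) / sum(data$n),
    stopped_at = res$stopped_at,
    overdispersed = res$dean$decision,
    dean_statistic = res$dean$statistic,
    moran_p = if (!is.null(res$moran)) res$moran$p_value else NA,
    chosen_model = if (best_is_bayes) {
      paste0("bayes_", res$best_structure)
    } else paste0("frequentist_", res$best_family),
    chosen_variables = if (best_is_bayes) {
      res$car[[res$best_structure]]$selected
    } else if (!is.null(res$negbin)) res$negbin$selected
      else res$poisson$selected,
    criterion = if (best_is_bayes) best$dic else best$aic,
    n_hotspots = if (!is.null(res$hotspots)) sum(res$hotspots$hotspot)
      else NA_integer_)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Small-area prevalence pipeline\n")
  cat(sprintf(" %d areas, %d cases (crude prevalence %.3f%%)\n",
              s$n_areas, s$total_cases, s$crude_prevalence_percent))
  cat(" stages run:", paste(x$stages, collapse = " -> "), "\n")
  cat(sprintf(" Dean statistic %.2f -> %s\n", s$dean_statistic,
              if (s$overdispersed) "overdispersed" else "equidispersed"))
  if (!is.null(x$moran)) {
    cat(sprintf(" Moran's I p = %.3f -> %s\n", s$moran_p,
                if (x$moran$decision) "residual autocorrelation"
                else "no autocorrelation"))
  }
  cat(" chosen model:", s$chosen_model,
      if (length(s$chosen_variables)) {
        paste0("(", paste(s$chosen_variables, collapse = "+"), ")")
      } else "(base)",
      sprintf("criterion %.2f", s$criterion), "\n")
  if (!is.na(s$n_hotspots)) cat(" hotspots flagged:", s$n_hotspots, "\n")
  invisible(x)
}
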