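# Cross-paradigm model comparison: variance explained, RMSD, ranked
# criterion tables.

#' Coefficient of determination between observed and fitted values
#'
#' Squared Pearson correlation of observed and fitted per-area values.
#' This definition is guaranteed to lie in \code{[0, 1]} for fits that are
#' not least-squares projections (GLM and posterior fitted values), which
#' is why it is the canonical one here; the \code{1 - SSE/SST} variant is
#' also returned as an attribute for reference.
#'
#' @param observed,fitted aligned numeric vectors, at least 3 areas,
#'   neither constant.
#' @return squared correlation, with attribute \code{"r2_sse"}.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("lengths differ")
  if (length(observed) < 3L) stop("need at least 3 areas")
  if (stats::sd(observed) == 0 || stats::sd(fitted) == 0) {
    stop("constant vector: correlation undefined")
  }
  r2 <- stats::cor(observed, fitted)^2
  attr(r2, "r2_sse") <- 1 - sum((observed - fitted)^2) /
    sum((observed - mean(observed))^2)
  r2
}

#' Root mean squared deviation between fitted and observed values
#'
#' @param observed,fitted aligned numeric vectors.
#' @return \code{sqrt(mean((fitted - observed)^2))}.
#' @export
rmsd <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("lengths differ")
  sqrt(mean((fitted - observed)^2))
}

#' Fitted/observed ratio per area
#'
#' Map-ready ratio of model fitted values to observed counts; areas with
#' zero observed count are returned as \code{NA} rather than infinite.
#'
#' @param observed,fitted aligned numeric vectors.
#' @return numeric vector of ratios.
#' @export
fitted_observed_ratio <- function(observed, fitted) {
  ifelse(observed > 0, fitted / observed, NA_real_)
}

model_criterion <- function(fit) {
  if (inherits(fit, "carfit")) c(value = fit$dic, type = "DIC")
  else if (inherits(fit, "glm_fit")) c(value = fit$aic, type = "AIC")
  else stop("unsupported fit object")
}

model_label <- function(fit) {
  if (inherits(fit, "carfit")) toupper(fit$structure) else fit$family
}

model_terms <- function(fit) {
  tt <- if (inherits(fit, "carfit")) fit$or_table$term else
    fit$or_table$term
  setdiff(tt, "(Intercept)")
}

#' Ranked model comparison table
#'
#' Builds the usual model-comparison report: one row per fitted model
#' (family/structure, explanatory variables, criterion value), sorted by
#' ascending criterion with the best model flagged. All fits must carry
#' the same criterion type: AIC (frequentist) and DIC (Bayesian) are not
#' comparable and mixing them is an error.
#'
#' @param fits list of \code{glm_fit} and/or \code{carfit} objects.
#' @param labels optional row labels.
#' @return data.frame with columns \code{model}, \code{variables},
#'   \code{criterion_type}, \code{criterion}, \code{n_terms}, \code{best}.
#' @export
model_table <- function(fits, labels = NULL) {
  stopifnot(length(fits) >= 1)
  crit <- lapply(fits, model_criterion)
  types <- vapply(crit, `[[`, "", "type")
  if (length(unique(types)) > 1) {
    stop("cannot rank AIC and DIC in a single table")
  }
  vars <- vapply(fits, function(f) {
    v <- model_terms(f)
    if (length(v)) paste(v, collapse = "+") else "(base)"
  }, "")
  tab <- data.frame(
    model = if (is.null(labels)) vapply(fits, model_label, "") else labels,
    variables = vars,
    criterion_type = types,
    criterion = vapply(crit, function(x) as.numeric(x[["value"]]), 0),
    n_terms = vapply(fits, function(f) length(model_terms(f)), 0L))
  # ascending criterion; ties favour the smaller model
  ord <- order(tab$criterion, tab$n_terms)
  tab <- tab[ord, ]
  tab$best <- FALSE
  tab$best[1] <- TRUE
  rownames(tab) <- NULL
  tab
}
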