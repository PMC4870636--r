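# Plain-text exports: CSV tables, edge lists, GeoJSON grid polygons,
# JSON run summaries.

#' Write an area dataset as CSV
#'
#' @param data an \code{\link{area_dataset}}.
#' @param path output file.
#' @export
write_area_data <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Read an area dataset written by \code{write_area_data}
#'
#' Rebuilds the \code{area_dataset} (expected counts are recomputed from
#' the stratum columns, preserving the internal-standardization
#' identity).
#'
#' @param path CSV file.
#' @param covariates covariate column names present in the file.
#' @param lattice optional \code{area_lattice} to reattach.
#' @return an \code{\link{area_dataset}}.
#' @export
read_area_data <- function(path, covariates = c("ECON", "MIG", "FRAG"),
                           lattice = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  strata <- as.matrix(df[, strata_names()])
  X <- as.matrix(df[, intersect(covariates, names(df)), drop = FALSE])
  area_dataset(df$y, strata, X = if (ncol(X)) X else NULL,
               lattice = lattice)
}

#' Write adjacency as an edge-list CSV
#'
#' One row per undirected edge, columns \code{area_i}, \code{area_j}
#' (1-based indices, \code{area_i < area_j}).
#'
#' @param W adjacency matrix or \code{area_lattice}.
#' @param path output file.
#' @export
write_adjacency_edges <- function(W, path) {
  utils::write.csv(adjacency_edges(W), path, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list CSV back into an adjacency matrix
#'
#' @param path edge-list CSV with columns \code{area_i}, \code{area_j}.
#' @param n number of areas (defaults to the largest index seen).
#' @return binary symmetric adjacency matrix.
#' @export
read_adjacency_edges <- function(path, n = NULL) {
  ed <- utils::read.csv(path)
  if (is.null(n)) n <- max(ed$area_i, ed$area_j)
  W <- matrix(0L, n, n)
  W[cbind(ed$area_i, ed$area_j)] <- 1L
  W[cbind(ed$area_j, ed$area_i)] <- 1L
  check_adjacency(W)
}

#' Write grid-cell polygons as GeoJSON
#'
#' Unit-square cell polygons for a grid lattice, with optional per-area
#' properties (e.g. a hotspot report) — a geometry-free stand-in for real
#' administrative boundaries, suitable for any GeoJSON viewer.
#'
#' @param lattice an \code{area_lattice} built by \code{\link{grid_lattice}}.
#' @param path output file.
#' @param properties optional data.frame of per-area properties.
#' @export
write_grid_geojson <- function(lattice, path, properties = NULL) {
  stopifnot(inherits(lattice, "area_lattice"))
  feats <- lapply(seq_len(lattice$n), function(k) {
    r <- (k - 1) %/% lattice$n_cols
    cc <- (k - 1) %% lattice$n_cols
    ring <- list(c(cc, -r), c(cc + 1, -r), c(cc + 1, -r - 1),
                 c(cc, -r - 1), c(cc, -r))
    props <- list(area_id = lattice$area_id[k])
    if (!is.null(properties)) {
      props <- c(props, as.list(properties[k, , drop = FALSE]))
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write retained MCMC chains as CSV
#'
#' One column per scalar parameter, one row per retained draw.
#'
#' @param fit a \code{carfit}.
#' @param path output file.
#' @export
write_chains_csv <- function(fit, path) {
  stopifnot(inherits(fit, "carfit"))
  utils::write.csv(as.data.frame(scalar_chains(fit$chains)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write fit metadata (priors, settings, diagnostics) as JSON
#'
#' @param fit a \code{carfit}.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "carfit"))
  meta <- list(structure = fit$structure,
               prior = unclass(fit$prior),
               mcmc = unclass(fit$mcmc)[c("n_burnin", "n_sample", "thin")],
               seed = fit$seed, dic = fit$dic, p_d = fit$p_d,
               geweke_z = as.list(fit$geweke),
               max_abs_geweke = max(abs(fit$geweke), na.rm = TRUE),
               acceptance = as.list(fit$acceptance[!is.na(fit$acceptance)]))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write model-summary and selection-trace tables for a pipeline run
#'
#' Emits the analysis artifact bundle into a directory: the area table,
#' selection traces (frequentist and per-structure Bayesian), effect
#' tables, the comparison table, the hotspot report (CSV, and GeoJSON if
#' a grid lattice is supplied) and a machine-readable JSON summary naming
#' the chosen model. Numbers are written at full precision.
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param dir output directory (created if missing).
#' @param data the \code{area_dataset} analysed (for the area table).
#' @param lattice optional \code{area_lattice} for the GeoJSON layer.
#' @return invisibly, the directory.
#' @export
write_pipeline <- function(result, dir, data = NULL, lattice = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  if (!is.null(data)) write_area_data(data, p("areas.csv"))
  utils::write.csv(result$poisson$trace, p("trace_poisson.csv"),
                   row.names = FALSE)
  if (!is.null(result$negbin)) {
    utils::write.csv(result$negbin$trace, p("trace_negbin.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$car)) {
    for (st in names(result$car)) {
      utils::write.csv(result$car[[st]]$trace,
                       p(sprintf("trace_car_%s.csv", st)),
                       row.names = FALSE)
    }
  }
  best <- if (!is.null(result$best_bayes)) result$best_bayes else
    result$best_freq
  utils::write.csv(best$or_table, p("best_model_effects.csv"),
                   row.names = FALSE)
  if (!is.null(result$comparison)) {
    utils::write.csv(result$comparison, p("comparison.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$hotspots)) {
    utils::write.csv(as.data.frame(result$hotspots), p("hotspots.csv"),
                     row.names = FALSE)
    if (!is.null(lattice)) {
      write_grid_geojson(lattice, p("hotspots.geojson"),
                         properties = as.data.frame(result$hotspots))
    }
  }
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write generative truth parameters as a JSON sidecar
#'
#' @param truth a \code{\link{generative_truth}}.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "generative_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
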