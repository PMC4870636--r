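#' Build a rectangular grid lattice with rook or queen adjacency
#'
#' Constructs the spatial skeleton used by the CAR priors and Moran's I: a
#' set of areas laid out on an \code{n_rows} by \code{n_cols} grid together
#' with a binary, symmetric, zero-diagonal adjacency matrix \code{W}.
#' Grid lattices stand in for administrative micro-neighbourhood units
#' (IRIS-type areas of roughly 2000 residents) whose true contiguity
#' structure is not public.
#'
#' @param n_rows,n_cols positive integers; the grid dimensions. The product
#'   must be at least 2.
#' @param adjacency_rule \code{"rook"} (shared edges; at most 4 neighbours)
#'   or \code{"queen"} (shared edges or corners; at most 8 neighbours).
#' @return An object of class \code{"area_lattice"}: a list with elements
#'   \code{W} (n x n binary adjacency matrix), \code{n}, \code{n_rows},
#'   \code{n_cols}, \code{adjacency_rule} and \code{area_id}.
#' @examples
#' lat <- grid_lattice(7, 8)        # 56 areas, rook moves
#' table(rowSums(lat$W))            # neighbour counts in {2,3,4}
#' @export
grid_lattice <- function(n_rows, n_cols, adjacency_rule = c("rook", "queen")) {
  adjacency_rule <- match.arg(adjacency_rule)
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("n_rows and n_cols must be positive integers")
  }
  n <- n_rows * n_cols
  if (n < 2) stop("degenerate grid: need at least 2 areas")

  # area k (1-based) sits at row r = (k-1) %/% n_cols + 1, col c = (k-1) %% n_cols + 1
  idx <- function(r, c) (r - 1L) * n_cols + c
  W <- matrix(0L, n, n)
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      k <- idx(r, cc)
      steps <- list(c(0L, 1L), c(1L, 0L))
      if (adjacency_rule == "queen") {
        steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
      }
      for (s in steps) {
        r2 <- r + s[1L]; c2 <- cc + s[2L]
        if (r2 >= 1L && r2 <= n_rows && c2 >= 1L && c2 <= n_cols) {
          k2 <- idx(r2, c2)
          W[k, k2] <- 1L
          W[k2, k] <- 1L
        }
      }
    }
  }
  structure(
    list(W = W, n = n, n_rows = n_rows, n_cols = n_cols,
         adjacency_rule = adjacency_rule,
         area_id = sprintf("A%03d", seq_len(n))),
    class = "area_lattice"
  )
}

#' @export
print.area_lattice <- function(x, ...) {
  cat("Area lattice:", x$n_rows, "x", x$n_cols, "grid (", x$n, "areas ),",
      x$adjacency_rule, "adjacency\n")
  cat("Neighbour counts:", paste(range(rowSums(x$W)), collapse = "-"),
      "; edges:", sum(x$W) / 2, "\n")
  invisible(x)
}

# Validate an adjacency matrix: binary, symmetric, zero diagonal.
# Every constructor and consumer funnels through this.
check_adjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("W must be a square matrix")
  }
  if (any(W != 0 & W != 1)) stop("W must be binary")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (any(W != t(W))) stop("W must be symmetric")
  invisible(W)
}

as_W <- function(x) {
  if (inherits(x, "area_lattice")) x$W else {
    check_adjacency(x)
    x
  }
}

# Edge list (i < j) of a binary symmetric adjacency matrix.
adjacency_edges <- function(W) {
  W <- as_W(W)
  ij <- which(W == 1 & upper.tri(W), arr.ind = TRUE)
  data.frame(area_i = ij[, 1L], area_j = ij[, 2L])
}

#' Check that the adjacency graph is connected
#'
#' @param W an adjacency matrix or \code{area_lattice}.
#' @return \code{TRUE} if every area is reachable from area 1.
#' @export
is_connected <- function(W) {
  W <- as_W(W)
  n <- nrow(W)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(W[frontier, , drop = FALSE] == 1) > 0)
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}
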