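# 3D graph layouts, unit-sphere projection and per-marker density grids.
# These are data exports; rendering is left to plotting front-ends.

#' 3D Kamada-Kawai layout of a cell graph
#'
#' Stress-minimising force-directed coordinates in 3D, seeded through the
#' random initial placement so a fixed `(graph, seed)` pair is reproducible.
#'
#' @param x an `mpx_projection` or a connected igraph
#' @param seed integer seed for the initial placement
#' @return numeric matrix (nodes x 3) with node-name rownames
#' @export
layout_3d <- function(x, seed = 1L) {
  g <- if (inherits(x, "mpx_projection")) x$graph else x
  n <- igraph::vcount(g)
  if (n < 1L) stop("empty graph")
  if (n == 1L) {
    warning("single-node graph: placed at a fixed point")
    coords <- matrix(c(1e-6, 0, 0), 1, 3)
    rownames(coords) <- igraph::V(g)$name
    colnames(coords) <- c("x", "y", "z")
    return(coords)
  }
  if (igraph::components(g)$no != 1L) {
    stop("graph must be connected")
  }
  set.seed(seed)
  init <- matrix(stats::runif(n * 3, -1, 1), ncol = 3)
  coords <- igraph::layout_with_kk(g, coords = init, dim = 3)
  rownames(coords) <- igraph::V(g)$name
  colnames(coords) <- c("x", "y", "z")
  coords
}

#' Project layout coordinates onto the unit sphere
#'
#' Coordinates are first centred on their centroid (so asymmetric layouts do
#' not collapse onto one hemisphere), then divided by their Euclidean norm.
#' A node landing exactly on the centroid is nudged by a small epsilon.
#'
#' @param coords nodes x 3 coordinate matrix
#' @return nodes x 3 matrix of unit-norm coordinates
#' @export
sphere_project <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  centred <- sweep(coords, 2, colMeans(coords))
  nrm <- sqrt(rowSums(centred^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    warning(sum(zero), " node(s) at the centroid nudged by epsilon")
    centred[zero, 1] <- 1e-9
    nrm[zero] <- sqrt(rowSums(centred[zero, , drop = FALSE]^2))
  }
  out <- centred / nrm
  rownames(out) <- rownames(coords)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Quasi-uniform grid on the unit sphere
#'
#' Fibonacci-lattice points covering the sphere; the default 2,000 points
#' give a grid spacing well below the default density kernel cutoff.
#'
#' @param n number of grid points
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n = 2000L) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Per-marker density heatmap on the unit sphere
#'
#' For every grid point and marker, nodes within `distance_cutoff` (Euclidean
#' chord distance) contribute `count * (1 - d / distance_cutoff)`; the colour
#' value is the natural log of that sum, and grid points receiving no mass
#' are `NA` (masked).
#'
#' @param unit_coords nodes x 3 unit-sphere coordinates ([sphere_project()])
#' @param counts nodes x markers count matrix (dense or sparse), rownames
#'   matching `unit_coords`
#' @param distance_cutoff kernel support radius (chord length)
#' @param grid grid points (defaults to [fibonacci_sphere()])
#' @return tibble `grid_id`, `x`, `y`, `z`, `marker`, `value`
#' @export
density_grid <- function(unit_coords, counts, distance_cutoff = 0.3,
                         grid = fibonacci_sphere()) {
  if (distance_cutoff <= 0) stop("distance_cutoff must be positive")
  counts <- as.matrix(counts)
  stopifnot(nrow(unit_coords) == nrow(counts))
  # chord distance via the Gram matrix: d^2 = 2 - 2 g.c for unit vectors;
  # computed as exact Euclidean distance so non-unit grids also work
  g2 <- rowSums(grid^2)
  n2 <- rowSums(unit_coords^2)
  d2 <- outer(g2, n2, "+") - 2 * grid %*% t(unit_coords)
  d <- sqrt(pmax(d2, 0))
  kernel <- 1 - d / distance_cutoff
  kernel[d >= distance_cutoff] <- 0
  s <- kernel %*% counts # grid x markers
  value <- ifelse(s > 0, log(s), NA_real_)
  ng <- nrow(grid)
  out <- tibble::tibble(
    grid_id = rep(seq_len(ng), times = ncol(counts)),
    x = rep(grid[, 1], times = ncol(counts)),
    y = rep(grid[, 2], times = ncol(counts)),
    z = rep(grid[, 3], times = ncol(counts)),
    marker = rep(colnames(counts), each = ng),
    value = as.numeric(value)
  )
  out
}

#' Export a cell layout with sphere projection as CSV
#'
#' @param proj an `mpx_projection`
#' @param path output CSV path
#' @param seed layout seed
#' @return tibble of node coordinates, invisibly (also written to `path`)
#' @export
write_layout <- function(proj, path, seed = 1L) {
  coords <- layout_3d(proj, seed = seed)
  unit <- sphere_project(coords)
  out <- tibble::tibble(node = rownames(coords),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        sx = unit[, 1], sy = unit[, 2], sz = unit[, 3])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
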