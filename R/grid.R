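#' Build a regular cubic source grid
#'
#' Source models for beamformer analyses place candidate sources on a regular
#' volumetric grid (the field standard is a 1-cm grid over the brain volume).
#' This builds an `n_per_axis`^3 cubic lattice together with its spatial
#' adjacency, which the cluster-based permutation tests use to define
#' connected clusters.
#'
#' @param n_per_axis Number of grid nodes per axis: a single integer for a
#'   cubic lattice, or a length-3 vector of per-axis counts. At least 2
#'   nodes in total.
#' @param spacing Distance between neighbouring nodes, in mm. Default 10.
#' @param neighbor_radius Two sources are adjacent when their Euclidean
#'   distance is at most this radius (mm). The default `1.01 * spacing`
#'   yields face adjacency (6 neighbours for an interior node).
#'
#' @return An object of class `source_grid`: a list with `positions`
#'   (n_sources x 3 matrix, mm), `spacing`, and `adjacency` (symmetric
#'   logical matrix with empty diagonal).
#' @examples
#' g <- build_source_grid(3, spacing = 10)
#' sum(g$adjacency[14, ]) # interior node of a 3x3x3 lattice: 6 neighbours
#' @export
build_source_grid <- function(n_per_axis, spacing = 10,
                              neighbor_radius = 1.01 * spacing) {
  if (!is.numeric(n_per_axis) || !length(n_per_axis) %in% c(1, 3) ||
      any(n_per_axis < 1) || any(n_per_axis != round(n_per_axis))) {
    abort("`n_per_axis` must be a positive integer (or a length-3 vector)")
  }
  if (length(n_per_axis) == 1) n_per_axis <- rep(n_per_axis, 3)
  if (prod(n_per_axis) < 2) abort("the grid needs at least 2 sources")
  check_number(spacing, "spacing", lo = .Machine$double.eps)
  check_number(neighbor_radius, "neighbor_radius", lo = 0)
  if (neighbor_radius < spacing) {
    warn("`neighbor_radius` is smaller than `spacing`: the grid has no adjacencies")
  }
  ax <- purrr::map(n_per_axis, ~ (seq_len(.x) - 1) * spacing)
  positions <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  d <- as.matrix(stats::dist(positions))
  adjacency <- d <= neighbor_radius & d > 0
  structure(
    list(positions = positions, spacing = spacing,
         neighbor_radius = neighbor_radius, adjacency = adjacency),
    class = "source_grid"
  )
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d sources, spacing %g mm, %d adjacency pairs\n",
              nrow(x$positions), x$spacing, sum(x$adjacency) / 2))
  invisible(x)
}

#' Posterior region of interest of a source grid
#'
#' The individual alpha frequency is identified over posterior
#' (occipito-temporal) locations. On the synthetic cubic grid "posterior" is
#' taken as the lowest `fraction` of nodes along one axis (default the y
#' axis).
#'
#' @param grid A [build_source_grid()] object.
#' @param fraction Fraction of the axis extent counted as posterior.
#' @param axis Axis index (1 = x, 2 = y, 3 = z).
#' @return Integer vector of source indices.
#' @export
roi_posterior <- function(grid, fraction = 1 / 3, axis = 2) {
  stopifnot(inherits(grid, "source_grid"))
  check_number(fraction, "fraction", lo = 1e-6, hi = 1)
  coord <- grid$positions[, axis]
  cutoff <- min(coord) + fraction * (max(coord) - min(coord))
  which(coord <= cutoff + 1e-9)
}

# Adjacency list form used by the cluster search (0-based neighbours are
# avoided; plain integer indices).
adjacency_list <- function(adjacency) {
  apply(adjacency, 1, which, simplify = FALSE)
}

# Connected components of a set of active nodes under a grid adjacency list.
# Returns a list of integer vectors (each a component of `active`).
connected_components <- function(active, adj_list) {
  if (length(active) == 0) return(list())
  in_active <- logical(length(adj_list))
  in_active[active] <- TRUE
  seen <- logical(length(adj_list))
  comps <- list()
  for (s in active) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj_list[[v]]
      nb <- nb[in_active[nb] & !seen[nb]]
      if (length(nb) > 0) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}
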