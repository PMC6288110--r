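#' Convex hull of a point cloud in d dimensions
#'
#' Exact hull volume and facet half-space representation, computed by an
#' incremental beneath-beyond algorithm. Point sets with fewer than `d + 1`
#' affinely independent points are degenerate: they enclose no
#' d-dimensional volume and are returned with `volume = 0` and
#' `degenerate = TRUE` (no reduced-rank volume is substituted, so volumes
#' stay dimensionally commensurable across assemblages). On numerical
#' failure the computation retries with a seeded joggle of magnitude
#' `1e-9` times the coordinate span.
#'
#' @param points numeric matrix (rows = points, columns = dimensions,
#'   `d >= 2`); row names are carried into `vertex_labels`.
#' @return an object of class `hull_result`: list with `volume`,
#'   `vertex_labels`, `vertices` (row indices), `normals` (facet unit
#'   normals), `offsets` (facet offsets, `normal . x <= offset` inside),
#'   `n_points`, `degenerate`, `joggled`.
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points)) stop("points must be numeric")
  if (ncol(points) < 2L) stop("need at least 2 dimensions")
  if (nrow(points) == 0L) stop("empty point set")
  storage.mode(points) <- "double"

  degen_result <- function() {
    structure(list(volume = 0, vertex_labels = character(0),
                   vertices = integer(0), normals = NULL, offsets = NULL,
                   n_points = nrow(points), degenerate = TRUE,
                   joggled = FALSE),
              class = "hull_result")
  }
  if (nrow(points) < ncol(points) + 1L) return(degen_result())

  res <- .chull_cpp(points, TRUE)
  joggled <- FALSE
  if (!res$ok) {
    # deterministic seeded joggle, preserving the caller's RNG state
    span <- max(apply(points, 2, function(x) diff(range(x))), 1e-300)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    for (attempt in 1:5) {
      set.seed(89001L + attempt)
      jog <- matrix(runif(length(points), -1, 1), nrow(points)) *
        span * 1e-9 * attempt
      res <- .chull_cpp(points + jog, TRUE)
      if (res$ok) { joggled <- TRUE; break }
    }
    if (!res$ok) stop("convex hull computation failed after joggle retries")
  }
  if (res$degenerate) return(degen_result())
  structure(list(volume = res$volume,
                 vertex_labels = rownames(points)[res$vertices],
                 vertices = res$vertices,
                 normals = res$normals, offsets = res$offsets,
                 n_points = nrow(points), degenerate = FALSE,
                 joggled = joggled),
            class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  if (x$degenerate)
    cat("Convex hull: degenerate (", x$n_points, "points, volume 0 )\n")
  else
    cat("Convex hull:", x$n_points, "points,",
        length(x$vertices), "vertices, volume", signif(x$volume, 6), "\n")
  invisible(x)
}

# volume only, no facet marshalling; used in tight null-model loops
hull_volume_fast <- function(points) {
  if (nrow(points) < ncol(points) + 1L) return(0)
  res <- .chull_cpp(points, FALSE)
  if (!res$ok) return(convex_hull_volume(points)$volume)
  res$volume
}

#' Test points for hull membership
#'
#' @param points numeric matrix of query points.
#' @param hull a non-degenerate `hull_result`.
#' @param tol boundary tolerance.
#' @return logical vector.
#' @export
points_in_hull <- function(points, hull, tol = 1e-9) {
  if (hull$degenerate) stop("membership in a degenerate hull is undefined")
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .points_in_hull_cpp(points, hull$normals, hull$offsets, tol)
}

#' Monte-Carlo hull volume (rejection sampling oracle)
#'
#' Estimates the hull volume by uniform rejection sampling over the
#' bounding box, with a standard error. Intended as an independent check
#' of the exact computation, not for production use.
#'
#' @param points point cloud defining the hull.
#' @param n_samples number of uniform samples.
#' @return list with `volume`, `se`.
#' @export
mc_hull_volume <- function(points, n_samples = 1e6) {
  hull <- convex_hull_volume(points)
  if (hull$degenerate) return(list(volume = 0, se = 0))
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  box <- prod(hi - lo)
  d <- ncol(points)
  samples <- matrix(runif(n_samples * d), ncol = d)
  samples <- sweep(sweep(samples, 2, hi - lo, "*"), 2, lo, "+")
  inside <- points_in_hull(samples, hull, tol = 0)
  p <- mean(inside)
  list(volume = box * p, se = box * sqrt(p * (1 - p) / n_samples))
}

#' Functional richness of an assemblage relative to a pool
#'
#' The hull volume of the occupied FEs as a percentage of the pool hull
#' volume. A degenerate occupied hull (fewer than `d + 1` affinely
#' independent FEs) yields 0% with a warning; a degenerate pool is an
#' error.
#'
#' @param space a `functional_space`.
#' @param occupied character vector of occupied FE labels.
#' @param pool character vector of pool FE labels (default: all).
#' @return list with `volume`, `pool_volume`, `pct_volume`, `hull`.
#' @export
functional_richness <- function(space, occupied, pool = space$labels) {
  stopifnot(inherits(space, "functional_space"))
  if (!all(occupied %in% pool)) stop("occupied FEs must be a subset of the pool")
  if (!all(pool %in% space$labels)) stop("pool FEs missing from the space")
  pool_hull <- convex_hull_volume(space$coords[pool, , drop = FALSE])
  if (pool_hull$degenerate) stop("degenerate pool hull")
  hull <- convex_hull_volume(space$coords[occupied, , drop = FALSE])
  if (hull$degenerate)
    warning("degenerate occupied hull; functional richness reported as 0%")
  list(volume = hull$volume, pool_volume = pool_hull$volume,
       pct_volume = 100 * hull$volume / pool_hull$volume, hull = hull)
}

#' Per-zone richness summary against the global pool
#'
#' @param space a `functional_space` built on the pool's FEs.
#' @param assemblages named list of `zone_assemblage` (see
#'   [aggregate_zones()]).
#' @param n_pool_species species count of the global pool.
#' @return data frame with one row per zone: species and FE counts, pool
#'   percentages ([pool_percentage()]), hull volume and `pct_volume`.
#' @export
richness_summary <- function(space, assemblages, n_pool_species) {
  partition <- space$partition
  if (is.null(partition)) stop("space carries no FE partition")
  n_pool_fes <- length(space$labels)
  rows <- lapply(assemblages, function(a) {
    occ <- occupied_fes(a, partition)
    fr <- functional_richness(space, occ)
    data.frame(zone = a$zone,
               n_species = length(a$species_present),
               n_fes = length(occ),
               pct_species = pool_percentage(length(a$species_present),
                                             n_pool_species),
               pct_fes = pool_percentage(length(occ), n_pool_fes),
               hull_volume = fr$volume,
               pct_volume = fr$pct_volume,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
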