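#' Jaccard dissimilarity partitioned into turnover and nestedness
#'
#' For shared magnitude `a` and unique magnitudes `b`, `c` (species counts
#' for taxonomic mode, hypervolumes for functional mode):
#' total `(b + c) / (a + b + c)`, turnover `2 min(b,c) / (a + 2 min(b,c))`,
#' nestedness-resultant = total - turnover. The partition is additive and
#' all three components lie in `[0, 1]`.
#'
#' @param a magnitude shared by both assemblages.
#' @param b magnitude unique to the first assemblage.
#' @param c magnitude unique to the second assemblage.
#' @return named numeric vector `total`, `turnover`, `nestedness`.
#' @export
jaccard_partition <- function(a, b, c) {
  if (any(c(a, b, c) < 0)) stop("components must be non-negative")
  if (a + b + c <= 0) stop("all components are zero")
  total <- (b + c) / (a + b + c)
  m <- min(b, c)
  turnover <- if (m == 0) 0 else 2 * m / (a + 2 * m)
  c(total = total, turnover = turnover, nestedness = total - turnover)
}

#' Taxonomic beta-diversity between two zone assemblages
#'
#' Presence/absence Jaccard dissimilarity partitioned into turnover and
#' nestedness-resultant components.
#'
#' @param zoneA,zoneB `zone_assemblage` objects (or character vectors of
#'   species).
#' @return an object of class `beta_partition` with `mode = "taxonomic"`,
#'   the three components, and the counts `a`, `b`, `c`.
#' @export
taxonomic_beta <- function(zoneA, zoneB) {
  spA <- if (inherits(zoneA, "zone_assemblage")) zoneA$species_present else zoneA
  spB <- if (inherits(zoneB, "zone_assemblage")) zoneB$species_present else zoneB
  if (!length(spA) || !length(spB)) stop("empty assemblage")
  a <- length(intersect(spA, spB))
  b <- length(setdiff(spA, spB))
  c <- length(setdiff(spB, spA))
  part <- if (a + b + c > 0 && b + c == 0)
    c(total = 0, turnover = 0, nestedness = 0)
  else jaccard_partition(a, b, c)
  structure(list(mode = "taxonomic", total = part[["total"]],
                 turnover = part[["turnover"]],
                 nestedness = part[["nestedness"]],
                 a = a, b = b, c = c, method = "sets"),
            class = "beta_partition")
}

# interior point of {x : normals x <= offsets} approximately maximizing the
# minimal slack: the piecewise-linear max violation is smoothed by
# log-sum-exp at a decreasing temperature and minimized by BFGS (the
# objective is smooth and convex at every temperature)
interior_point <- function(normals, offsets, bbox_lo, bbox_hi) {
  span <- max(bbox_hi - bbox_lo)
  x <- (bbox_lo + bbox_hi) / 2
  for (tau in span * c(0.3, 0.1, 0.03, 0.01, 0.003, 1e-3, 3e-4, 1e-4, 3e-5)) {
    fn <- function(x) {
      s <- (as.vector(normals %*% x) - offsets) / tau
      m <- max(s)
      tau * (m + log(sum(exp(s - m))))
    }
    gr <- function(x) {
      s <- (as.vector(normals %*% x) - offsets) / tau
      w <- exp(s - max(s))
      as.vector(t(normals) %*% (w / sum(w)))
    }
    x <- stats::optim(x, fn, gr, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-13))$par
  }
  list(x = x, slack = min(offsets - as.vector(normals %*% x)))
}

#' Volume of the intersection of two convex hulls
#'
#' Exact mode: the intersection polytope is the set of points satisfying
#' the facet inequalities of both hulls. A strictly interior point is found
#' by maximizing the minimal slack (a smoothed minimax solved by BFGS, the
#' continuous analogue of the usual phase-one linear program); if none exists
#' the hulls do not overlap and the volume is 0. Otherwise the half-space
#' intersection is converted to vertices by polar duality about the
#' interior point (the dual convex hull's facets map to primal vertices)
#' and the volume of those vertices' hull is returned. Monte-Carlo mode
#' (also the automatic fallback on numerical failure) rejection-samples the
#' overlap of the two bounding boxes and tests membership in both hulls,
#' returning a standard error.
#'
#' @param pointsA,pointsB point clouds (rows = points) of the two hulls,
#'   same dimension, each non-degenerate.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_samples Monte-Carlo sample count.
#' @return list with `volume`, `method`, and `mc_se` (NA for exact).
#' @export
hull_intersection_volume <- function(pointsA, pointsB,
                                     method = c("exact", "monte_carlo"),
                                     n_samples = 1e5) {
  method <- match.arg(method)
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  if (ncol(pointsA) != ncol(pointsB)) stop("dimension mismatch")
  hullA <- convex_hull_volume(pointsA)
  hullB <- convex_hull_volume(pointsB)
  if (hullA$degenerate || hullB$degenerate)
    stop("degenerate input hull; handle via functional_richness instead")

  # quick reject on disjoint bounding boxes
  loA <- apply(pointsA, 2, min); hiA <- apply(pointsA, 2, max)
  loB <- apply(pointsB, 2, min); hiB <- apply(pointsB, 2, max)
  lo <- pmax(loA, loB); hi <- pmin(hiA, hiB)
  if (any(lo >= hi))
    return(list(volume = 0, method = method, mc_se = if (method == "exact") NA_real_ else 0))

  if (method == "exact") {
    out <- tryCatch(exact_intersection(hullA, hullB, lo, hi),
                    error = function(e) NULL)
    if (!is.null(out))
      return(list(volume = out, method = "exact", mc_se = NA_real_))
    method <- "monte_carlo" # numerical fallback
  }

  d <- ncol(pointsA)
  box <- prod(hi - lo)
  samples <- matrix(runif(n_samples * d), ncol = d)
  samples <- sweep(sweep(samples, 2, hi - lo, "*"), 2, lo, "+")
  inside <- points_in_hull(samples, hullA, tol = 0) &
    points_in_hull(samples, hullB, tol = 0)
  p <- mean(inside)
  list(volume = box * p, method = "monte_carlo",
       mc_se = box * sqrt(p * (1 - p) / n_samples))
}

exact_intersection <- function(hullA, hullB, lo, hi) {
  normals <- rbind(hullA$normals, hullB$normals)
  offsets <- c(hullA$offsets, hullB$offsets)
  dup <- duplicated(round(cbind(normals, offsets), 12))
  normals <- normals[!dup, , drop = FALSE]
  offsets <- offsets[!dup]
  span <- max(hi - lo)
  ip <- interior_point(normals, offsets, lo, hi)
  if (ip$slack <= 1e-8 * span) return(0) # empty or lower-dimensional overlap
  x0 <- ip$x
  # polar dual: half-space a.x <= b with x0 interior -> dual point a/(b - a.x0)
  slack <- offsets - as.vector(normals %*% x0)
  dual <- normals / slack
  dual_hull <- convex_hull_volume(dual)
  if (dual_hull$degenerate) return(0)
  # dual facet u.y <= c (c > 0, origin interior) -> primal vertex x0 + u/c
  keep <- dual_hull$offsets > 1e-12
  verts <- dual_hull$normals[keep, , drop = FALSE] / dual_hull$offsets[keep]
  verts <- sweep(verts, 2, x0, "+")
  convex_hull_volume(verts)$volume
}

#' Functional beta-diversity between two sets of functional entities
#'
#' The shared magnitude is the intersection volume of the two assemblages'
#' hulls in the functional space; unique magnitudes are each hull's volume
#' minus the intersection. The Jaccard partition is applied to these
#' hypervolumes. `nested_fraction_A` (`_B`) is the fraction of A's (B's)
#' hull volume lying inside the other hull — the "proportion of the
#' functional richness of A nested in B".
#'
#' @param space a `functional_space`.
#' @param fesA,fesB character vectors of occupied FE labels.
#' @param method,n_samples passed to [hull_intersection_volume()].
#' @return a `beta_partition` with `mode = "functional"`, hypervolume
#'   components `a`, `b`, `c`, and nested fractions.
#' @export
functional_beta <- function(space, fesA, fesB,
                            method = c("exact", "monte_carlo"),
                            n_samples = 1e5) {
  method <- match.arg(method)
  stopifnot(inherits(space, "functional_space"))
  pa <- space$coords[fesA, , drop = FALSE]
  pb <- space$coords[fesB, , drop = FALSE]
  inter <- hull_intersection_volume(pa, pb, method = method,
                                    n_samples = n_samples)
  vA <- convex_hull_volume(pa)$volume
  vB <- convex_hull_volume(pb)$volume
  a <- min(inter$volume, vA, vB) # clip MC noise
  b <- max(vA - a, 0)
  c <- max(vB - a, 0)
  part <- if (b + c <= max(1e-12 * max(vA, vB), 0))
    c(total = 0, turnover = 0, nestedness = 0)
  else jaccard_partition(a, b, c)
  structure(list(mode = "functional", total = part[["total"]],
                 turnover = part[["turnover"]],
                 nestedness = part[["nestedness"]],
                 a = a, b = b, c = c, method = inter$method,
                 mc_se = inter$mc_se,
                 nested_fraction_A = a / vA, nested_fraction_B = a / vB),
            class = "beta_partition")
}

#' Fraction of one assemblage's functional richness nested in another's
#'
#' `V(inner hull intersected with outer hull) / V(inner hull)`: 1 when the
#' inner assemblage's functional space is entirely contained in the
#' outer's.
#'
#' @param space a `functional_space`.
#' @param inner,outer character vectors of occupied FE labels.
#' @param ... passed to [hull_intersection_volume()].
#' @return a proportion in `[0, 1]`.
#' @export
nested_fraction <- function(space, inner, outer, ...) {
  pi_ <- space$coords[inner, , drop = FALSE]
  po <- space$coords[outer, , drop = FALSE]
  v <- convex_hull_volume(pi_)$volume
  if (v == 0) stop("degenerate inner hull")
  min(1, hull_intersection_volume(pi_, po, ...)$volume / v)
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("%s beta-diversity (%s): total %.3f = turnover %.3f + nestedness %.3f\n",
              x$mode, x$method, x$total, x$turnover, x$nestedness))
  invisible(x)
}

#' Pairwise beta-diversity table over zone assemblages
#'
#' One row per unordered zone pair and mode (taxonomic and functional).
#'
#' @param space a `functional_space` (with partition).
#' @param assemblages named list of `zone_assemblage`.
#' @param method passed to [functional_beta()].
#' @return data frame with columns `zone_a`, `zone_b`, `mode`, `total`,
#'   `turnover`, `nestedness`, `a`, `b`, `c`, `method`.
#' @export
beta_pairs <- function(space, assemblages, method = "exact") {
  zones <- names(assemblages)
  rows <- list()
  for (i in seq_along(zones)) for (j in seq_along(zones)) {
    if (j <= i) next
    A <- assemblages[[i]]; B <- assemblages[[j]]
    tb <- taxonomic_beta(A, B)
    fb <- functional_beta(space,
                          occupied_fes(A, space$partition),
                          occupied_fes(B, space$partition),
                          method = method)
    for (p in list(tb, fb))
      rows[[length(rows) + 1L]] <- data.frame(
        zone_a = zones[i], zone_b = zones[j], mode = p$mode,
        total = p$total, turnover = p$turnover, nestedness = p$nestedness,
        a = p$a, b = p$b, c = p$c, method = p$method,
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
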