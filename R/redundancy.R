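#' Neighbourhood functional redundancy profile of a zone
#'
#' Ripley's-k-style redundancy: for each occupied FE, the number of species
#' (and their summed relative cover) belonging to occupied FEs whose
#' coordinates lie within a fixed radius of it in the functional space. The
#' radius is `k_frac` times the maximum pairwise distance among the
#' *global pool's* FEs, so radii are comparable across zones; the boundary
#' is inclusive. An FE always counts its own members, so
#' `n_species_within >= 1`.
#'
#' @param space a `functional_space` built on the pool's FEs.
#' @param partition the `fe_partition` (default: the space's own).
#' @param assemblage a `zone_assemblage`.
#' @param k_frac radius as a fraction of the maximum FE-pair distance
#'   (default 0.01, i.e. 1%).
#' @return an object of class `redundancy_profile`: list with `zone`,
#'   `radius`, `k_frac`, `per_fe` (data frame: `fe_id`,
#'   `n_species_within`, `abundance_within` in % of the zone's total
#'   cover), and `vulnerability`.
#' @export
redundancy_profile <- function(space, partition = space$partition,
                               assemblage, k_frac = 0.01) {
  stopifnot(inherits(space, "functional_space"))
  if (is.null(partition)) stop("no FE partition available")
  sp <- assemblage$species_present
  missing <- setdiff(sp, names(partition$species_to_fe))
  if (length(missing))
    stop("species missing from FE partition: ",
         paste(missing, collapse = ", "))
  occ <- sort(unique(unname(partition$species_to_fe[sp])))
  if (!length(occ)) stop("no occupied FEs")
  radius <- k_frac * max(dist(space$coords)) # pool-wide normalizer

  # per occupied FE: present members and their zone cover
  cover <- assemblage$mean_cover[sp]
  fe_of <- partition$species_to_fe[sp]
  n_present <- tapply(rep(1L, length(sp)), fe_of, sum)[occ]
  cov_fe <- tapply(cover, fe_of, sum)[occ]
  total_cover <- sum(cover)

  dmat <- as.matrix(dist(space$coords[occ, , drop = FALSE]))
  within <- dmat <= radius + 1e-12
  n_species_within <- as.integer(within %*% n_present)
  abundance_within <- 100 * as.vector(within %*% cov_fe) / total_cover

  per_fe <- data.frame(fe_id = occ,
                       n_species_within = n_species_within,
                       abundance_within = abundance_within,
                       stringsAsFactors = FALSE)
  structure(list(zone = assemblage$zone, radius = radius, k_frac = k_frac,
                 per_fe = per_fe, n_species_present = length(sp),
                 vulnerability = mean(n_species_within == 1L)),
            class = "redundancy_profile")
}

#' Functional vulnerability of a redundancy profile
#'
#' The proportion of occupied FEs supported by a single species within the
#' k radius — functions with no insurance.
#'
#' @param profile a `redundancy_profile`.
#' @return a proportion in `[0, 1]`.
#' @export
vulnerability <- function(profile) {
  stopifnot(inherits(profile, "redundancy_profile"))
  mean(profile$per_fe$n_species_within == 1L)
}

#' Mean number of species per functional entity
#'
#' `mode = "naive"`: species count divided by FE count (accepts an
#' `fe_partition` or a `redundancy_profile` of a zone). `mode = "radius"`:
#' mean of `n_species_within` over occupied FEs (requires a profile).
#'
#' @param x an `fe_partition` or `redundancy_profile`.
#' @param mode `"naive"` or `"radius"`.
#' @return mean count.
#' @export
mean_species_per_fe <- function(x, mode = c("naive", "radius")) {
  mode <- match.arg(mode)
  if (inherits(x, "fe_partition")) {
    if (mode == "radius")
      stop("radius mode needs a redundancy_profile")
    return(length(x$species_to_fe) / length(x$entities))
  }
  stopifnot(inherits(x, "redundancy_profile"))
  if (mode == "radius") return(mean(x$per_fe$n_species_within))
  x$n_species_present / nrow(x$per_fe)
}

#' @export
print.redundancy_profile <- function(x, ...) {
  cat(sprintf(paste0("Redundancy profile (zone '%s', k = %.3g%% -> radius %.4g):\n",
                     "  %d occupied FEs | mean species within radius %.2f | ",
                     "vulnerability %.3f\n"),
              x$zone, 100 * x$k_frac, x$radius, nrow(x$per_fe),
              mean(x$per_fe$n_species_within), x$vulnerability))
  invisible(x)
}
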