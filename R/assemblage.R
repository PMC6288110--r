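ZONES <- c("ambient", "low", "extreme_low")
SITES <- c("north", "south")

#' Convert grid counts to per-cent cover
#'
#' Quadrats are scored on a grid (25 squares of 5 cm x 5 cm in the standard
#' 25 cm x 25 cm design); cover is the percentage of squares filled.
#'
#' @param filled_squares number of squares filled by the species.
#' @param total_squares number of squares in the grid (default 25).
#' @return per-cent cover, `100 * filled / total`.
#' @export
grid_to_percent_cover <- function(filled_squares, total_squares = 25L) {
  if (any(total_squares <= 0)) stop("total_squares must be positive")
  if (any(filled_squares < 0)) stop("negative filled_squares")
  if (any(filled_squares > total_squares))
    stop("filled_squares exceeds total_squares")
  100 * filled_squares / total_squares
}

#' Validate a long-format survey table
#'
#' @param surveys data frame with columns `quadrat_id`, `site`, `zone`,
#'   `species`, `cover` (per-cent, non-negative). Zones must be among
#'   `ambient`, `low`, `extreme_low`; sites among `north`, `south`.
#' @return the validated data frame.
#' @export
validate_surveys <- function(surveys) {
  need <- c("quadrat_id", "site", "zone", "species", "cover")
  missing <- setdiff(need, names(surveys))
  if (length(missing))
    stop("survey table lacks column(s): ", paste(missing, collapse = ", "))
  surveys <- as.data.frame(surveys)[need]
  bad <- setdiff(unique(surveys$zone), ZONES)
  if (length(bad)) stop("unknown zone(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(surveys$site), SITES)
  if (length(bad)) stop("unknown site(s): ", paste(bad, collapse = ", "))
  if (any(is.na(surveys$cover) | surveys$cover < 0))
    stop("covers must be non-negative and non-missing")
  surveys
}

#' Read quadrat cover tables
#'
#' `read_cover_long()` reads a long table (`quadrat_id`, `site`, `zone`,
#' `species`, `cover`). `read_cover_wide()` reads a quadrats-by-species
#' matrix (first column `quadrat_id`) plus a sidecar metadata table
#' (`quadrat_id`, `site`, `zone`).
#'
#' @param path file path (CSV, or TSV for `.tsv`/`.txt`).
#' @return a validated long-format survey data frame.
#' @export
read_cover_long <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 fileEncoding = "UTF-8")
  df$cover <- as.numeric(df$cover)
  validate_surveys(df)
}

#' @rdname read_cover_long
#' @param meta_path path to the quadrat metadata sidecar.
#' @export
read_cover_wide <- function(path, meta_path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  wide <- read.csv(path, sep = sep, check.names = FALSE,
                   fileEncoding = "UTF-8")
  names(wide)[1] <- "quadrat_id"
  meta <- read.csv(meta_path, sep = sep, check.names = FALSE,
                   fileEncoding = "UTF-8")
  sp <- setdiff(names(wide), "quadrat_id")
  long <- data.frame(
    quadrat_id = rep(wide$quadrat_id, times = length(sp)),
    species = rep(sp, each = nrow(wide)),
    cover = as.numeric(unlist(wide[sp], use.names = FALSE)),
    stringsAsFactors = FALSE)
  long <- long[long$cover > 0, ]
  long <- merge(long, meta[c("quadrat_id", "site", "zone")],
                by = "quadrat_id")
  validate_surveys(long)
}

#' Write a long-format survey table
#' @param surveys validated survey data frame.
#' @param path file path.
#' @export
write_cover_long <- function(surveys, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(validate_surveys(surveys), path, sep = sep,
              row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pool quadrats into a zone assemblage
#'
#' Quadrats from both sites are pooled per zone; a species' zone abundance
#' is its arithmetic mean cover over the zone's quadrats, counting quadrats
#' where it is absent as zero.
#'
#' @param surveys validated long-format survey table.
#' @param zone zone to aggregate (`ambient`, `low` or `extreme_low`).
#' @return an object of class `zone_assemblage`: list with `zone`,
#'   `mean_cover` (named, species with positive mean only),
#'   `species_present`, `n_quadrats`.
#' @export
aggregate_zone <- function(surveys, zone) {
  surveys <- validate_surveys(surveys)
  zs <- surveys[surveys$zone == zone, ]
  quads <- unique(zs$quadrat_id)
  if (length(quads) == 0L) stop("no quadrats in zone '", zone, "'")
  tot <- tapply(zs$cover, zs$species, sum)
  mean_cover <- tot / length(quads)
  mean_cover <- mean_cover[mean_cover > 0]
  mean_cover <- mean_cover[order(names(mean_cover))]
  structure(list(zone = zone,
                 mean_cover = c(mean_cover),
                 species_present = names(mean_cover),
                 n_quadrats = length(quads)),
            class = "zone_assemblage")
}

#' Aggregate every zone present in a survey table
#' @param surveys validated long-format survey table.
#' @return named list of `zone_assemblage`, in gradient order.
#' @export
aggregate_zones <- function(surveys) {
  zones <- intersect(ZONES, unique(surveys$zone))
  setNames(lapply(zones, function(z) aggregate_zone(surveys, z)), zones)
}

#' @export
print.zone_assemblage <- function(x, ...) {
  cat("Zone assemblage '", x$zone, "': ", length(x$species_present),
      " species over ", x$n_quadrats, " quadrats; total mean cover ",
      round(sum(x$mean_cover), 1), "%\n", sep = "")
  invisible(x)
}

#' Relative percentage of a pool, as printed in summaries
#'
#' `round(100 * count_in_zone / count_in_pool)` to the nearest integer
#' (IEC 60559 half-to-even tie-breaking, as in base [round()]).
#'
#' @param count_in_zone count in the assemblage.
#' @param count_in_pool count in the global pool (> 0).
#' @return integer percentage.
#' @export
pool_percentage <- function(count_in_zone, count_in_pool) {
  if (any(count_in_pool <= 0)) stop("pool count must be positive")
  if (any(count_in_zone < 0) || any(count_in_zone > count_in_pool))
    stop("zone count must lie in [0, pool count]")
  as.integer(round(100 * count_in_zone / count_in_pool))
}

#' Relative abundance of each category of one trait in a zone
#'
#' For each category of `trait`, 100 x (summed mean cover of the zone's
#' species carrying that category) / (summed mean cover of all present
#' species). All declared categories are reported (absent ones as 0), so
#' the values sum to 100.
#'
#' @param assemblage a `zone_assemblage`.
#' @param table validated trait table covering all present species.
#' @param trait trait name.
#' @param schema the `trait_schema`.
#' @return named numeric vector, one entry per declared category.
#' @export
trait_category_abundance <- function(assemblage, table, trait, schema) {
  if (!trait %in% names(schema)) stop("unknown trait '", trait, "'")
  table <- validate_trait_table(table, schema)
  sp <- assemblage$species_present
  missing <- setdiff(sp, table$species)
  if (length(missing))
    stop("species missing from trait table: ",
         paste(missing, collapse = ", "))
  val <- setNames(table[[trait]], table$species)[sp]
  w <- assemblage$mean_cover[sp]
  tot <- sum(w)
  out <- setNames(numeric(length(schema[[trait]]$categories)),
                  schema[[trait]]$categories)
  agg <- tapply(w, val, sum)
  out[names(agg)] <- 100 * agg / tot
  out
}

#' Relative cover of each functional entity in a zone
#'
#' Member mean covers are summed per FE and normalised to 100%.
#'
#' @param assemblage a `zone_assemblage`.
#' @param partition an `fe_partition` covering all present species.
#' @param dense if `TRUE`, report absent FEs as 0 instead of dropping them.
#' @return named numeric vector `fe_id` -> relative cover (%).
#' @export
fe_abundance_distribution <- function(assemblage, partition, dense = FALSE) {
  sp <- assemblage$species_present
  missing <- setdiff(sp, names(partition$species_to_fe))
  if (length(missing))
    stop("species missing from FE partition: ",
         paste(missing, collapse = ", "))
  fe <- partition$species_to_fe[sp]
  agg <- tapply(assemblage$mean_cover[sp], fe, sum)
  out <- 100 * agg / sum(agg)
  if (dense) {
    all_fe <- vapply(partition$entities, function(e) e$fe_id, "")
    full <- setNames(numeric(length(all_fe)), all_fe)
    full[names(out)] <- out
    out <- full
  }
  c(out)
}

#' Functional entities occupied by an assemblage
#' @param assemblage a `zone_assemblage`.
#' @param partition an `fe_partition`.
#' @return character vector of occupied `fe_id`s.
#' @export
occupied_fes <- function(assemblage, partition) {
  sort(unique(unname(partition$species_to_fe[assemblage$species_present])))
}
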