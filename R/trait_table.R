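#' Validate a species-by-trait table against a schema
#'
#' Checks that every schema trait is present as a column, every value is a
#' declared category of its trait, species identifiers are unique and no
#' value is missing. Columns are reordered to schema order.
#'
#' @param table data frame with a `species` column (or species in the first
#'   column) and one column per trait.
#' @param schema a `trait_schema`.
#' @return the validated table (data frame, columns `species` then traits in
#'   schema order, all character).
#' @export
validate_trait_table <- function(table, schema) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (!"species" %in% names(table)) names(table)[1] <- "species"
  missing <- setdiff(names(schema), names(table))
  if (length(missing))
    stop("missing trait column(s): ", paste(missing, collapse = ", "))
  table <- table[, c("species", names(schema)), drop = FALSE]
  table$species <- as.character(table$species)
  if (anyDuplicated(table$species))
    stop("duplicated species id(s): ",
         paste(unique(table$species[duplicated(table$species)]),
               collapse = ", "))
  if (nrow(table) == 0L) stop("empty trait table")
  for (tr in names(schema)) {
    v <- as.character(table[[tr]])
    if (anyNA(v) || any(!nzchar(v)))
      stop("missing value(s) for trait '", tr, "' (species ",
           paste(table$species[is.na(v) | !nzchar(v)], collapse = ", "), ")")
    bad <- !v %in% schema[[tr]]$categories
    if (any(bad))
      stop("invalid category for trait '", tr, "': species ",
           table$species[which(bad)[1]], " has code '", v[which(bad)[1]],
           "' (allowed: ", paste(schema[[tr]]$categories, collapse = ","), ")")
    table[[tr]] <- v
  }
  rownames(table) <- NULL
  table
}

#' Read / write species-by-trait tables
#'
#' Delimited text, UTF-8, header row naming the traits, first column the
#' species identifier. The separator is sniffed from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#'
#' @param path file path.
#' @param schema a `trait_schema` used for validation.
#' @param sep field separator, `NULL` to infer from the extension.
#' @return the validated trait table.
#' @export
read_trait_table <- function(path, schema, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 colClasses = "character", fileEncoding = "UTF-8")
  validate_trait_table(df, schema)
}

#' @rdname read_trait_table
#' @param table a validated trait table.
#' @export
write_trait_table <- function(table, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Group species into functional entities
#'
#' Functional entities (FEs) are the equivalence classes of exact
#' trait-vector equality. FE identifiers are deterministic: entities are
#' ordered lexicographically by trait vector (schema order) with the first
#' member name breaking ties, and labelled `FE001`, `FE002`, ...
#'
#' @param table a validated trait table.
#' @param schema the `trait_schema` the table validates against.
#' @return an object of class `fe_partition` with elements
#'   `entities` (list of `fe_id`, `trait_vector`, `members`),
#'   `species_to_fe` (named character vector), and `fe_table` (a trait
#'   table with one row per FE, species column = `fe_id`).
#' @export
build_functional_entities <- function(table, schema) {
  table <- validate_trait_table(table, schema)
  traits <- names(schema)
  key <- do.call(paste, c(table[traits], sep = "\r"))
  groups <- split(table$species, key)
  first_member <- vapply(groups, function(m) sort(m)[1], "")
  ord <- order(names(groups), first_member)
  groups <- groups[ord]
  ids <- sprintf("FE%03d", seq_along(groups))
  vec_of <- function(k) {
    v <- strsplit(k, "\r", fixed = TRUE)[[1]]
    setNames(v, traits)
  }
  entities <- lapply(seq_along(groups), function(i)
    list(fe_id = ids[i], trait_vector = vec_of(names(groups)[i]),
         members = sort(groups[[i]])))
  species_to_fe <- setNames(rep(ids, lengths(groups)), unlist(groups))
  species_to_fe <- species_to_fe[table$species]
  fe_table <- do.call(rbind, lapply(entities, function(e)
    data.frame(species = e$fe_id, as.list(e$trait_vector),
               check.names = FALSE, stringsAsFactors = FALSE)))
  structure(list(entities = entities, species_to_fe = species_to_fe,
                 fe_table = fe_table, traits = traits),
            class = "fe_partition")
}

#' @export
print.fe_partition <- function(x, ...) {
  sizes <- vapply(x$entities, function(e) length(e$members), 0L)
  cat("Functional-entity partition:", length(x$species_to_fe), "species in",
      length(x$entities), "FEs\n")
  cat("  singleton FEs:", sum(sizes == 1L),
      "| largest FE:", max(sizes), "species\n")
  invisible(x)
}

#' Number of functional entities
#' @param partition an `fe_partition`.
#' @return integer.
#' @export
n_fe <- function(partition) length(partition$entities)

#' Members of each functional entity
#' @param partition an `fe_partition`.
#' @return named list `fe_id` -> character vector of species.
#' @export
fe_members <- function(partition) {
  setNames(lapply(partition$entities, function(e) e$members),
           vapply(partition$entities, function(e) e$fe_id, ""))
}

#' Recode a trait table to its coarse categories
#'
#' Each value is replaced by its trait's `coarse_map` image; the result
#' validates against [coarse_schema()] of the same schema. Used for the
#' sensitivity analysis in which trait categories are merged (2--4 coarse
#' categories per trait) and every metric recomputed.
#'
#' @param table a validated trait table.
#' @param schema a `trait_schema` in which every trait has a `coarse_map`.
#' @return the recoded table, validated against the coarse schema.
#' @export
coarsen_traits <- function(table, schema) {
  table <- validate_trait_table(table, schema)
  for (tr in names(schema)) {
    cm <- schema[[tr]]$coarse_map
    if (is.null(cm)) stop("trait '", tr, "' has no coarse_map")
    table[[tr]] <- unname(cm[table[[tr]]])
  }
  validate_trait_table(table, coarse_schema(schema))
}
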