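#' Define a single functional trait
#'
#' A trait is categorical: `nominal` (unordered codes), `ordinal` (the order
#' of `categories` is meaningful and enters the Gower distance as scaled
#' ranks) or `binary` (two codes, treated like nominal). An optional
#' `coarse_map` recodes each category into a coarser category for
#' sensitivity analyses.
#'
#' @param name trait identifier (column name in trait tables).
#' @param kind one of `"nominal"`, `"ordinal"`, `"binary"`.
#' @param categories character vector of allowed category codes; for ordinal
#'   traits the vector order is the trait's total order.
#' @param coarse_map optional named character vector mapping every category
#'   to a coarse category.
#' @return an object of class `trait_def`.
#' @export
trait_def <- function(name, kind = c("nominal", "ordinal", "binary"),
                      categories, coarse_map = NULL) {
  kind <- match.arg(kind)
  categories <- as.character(categories)
  if (length(categories) < 1L) stop("trait '", name, "': no categories")
  if (anyDuplicated(categories))
    stop("trait '", name, "': duplicated categories")
  if (kind == "binary" && length(categories) != 2L)
    stop("trait '", name, "': binary traits need exactly 2 categories")
  if (!is.null(coarse_map)) {
    coarse_map <- vapply(coarse_map, as.character, "")
    missing <- setdiff(categories, names(coarse_map))
    if (length(missing))
      stop("trait '", name, "': coarse_map not total, missing: ",
           paste(missing, collapse = ", "))
    coarse_map <- coarse_map[categories]
  }
  structure(list(name = name, kind = kind, categories = categories,
                 coarse_map = coarse_map),
            class = "trait_def")
}

#' Assemble a trait schema
#'
#' @param traits list of [trait_def()] objects; their order is the canonical
#'   column order of validated trait tables.
#' @return an object of class `trait_schema` (named list of trait
#'   definitions).
#' @export
trait_schema <- function(traits) {
  if (!length(traits)) stop("empty schema")
  nm <- vapply(traits, function(t) t$name, "")
  if (anyDuplicated(nm)) stop("duplicated trait names in schema")
  structure(setNames(traits, nm), class = "trait_schema")
}

#' @export
print.trait_schema <- function(x, ...) {
  ncat <- sum(vapply(x, function(t) length(t$categories), 0L))
  cat("Trait schema:", length(x), "traits,", ncat, "categories\n")
  for (t in x)
    cat(sprintf("  %-22s %-8s {%s}%s\n", t$name, t$kind,
                paste(t$categories, collapse = ","),
                if (is.null(t$coarse_map)) "" else " [coarse map]"))
  invisible(x)
}

#' Total number of categories declared in a schema
#' @param schema a `trait_schema`.
#' @return integer count over all traits.
#' @export
n_categories <- function(schema) {
  sum(vapply(schema, function(t) length(t$categories), 0L))
}

#' Read / write trait schemas as YAML
#'
#' The YAML layout is a list of traits, each with `name`, `kind`,
#' `categories` (in order) and optionally `coarse_map`.
#'
#' @param path file path.
#' @return [read_trait_schema()] returns a `trait_schema`.
#' @export
read_trait_schema <- function(path) {
  y <- yaml::read_yaml(path)
  trait_schema(lapply(y$traits, function(t) {
    cm <- t$coarse_map
    if (!is.null(cm)) cm <- unlist(cm)
    trait_def(t$name, t$kind, as.character(unlist(t$categories)), cm)
  }))
}

#' @rdname read_trait_schema
#' @param schema a `trait_schema` to serialize.
#' @export
write_trait_schema <- function(schema, path) {
  y <- list(traits = lapply(unname(schema), function(t) {
    out <- list(name = t$name, kind = t$kind,
                categories = as.list(t$categories))
    if (!is.null(t$coarse_map)) out$coarse_map <- as.list(t$coarse_map)
    out
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The bundled 15-trait benthic schema
#'
#' A machine-readable schema of 15 functional traits (73 categories in
#' total) describing shallow rocky-reef benthic algae and invertebrates:
#' morphological form, solitary--colonial life history, maximum longevity,
#' height, width, epibiosis, energetic resource, photosynthetic pigments,
#' feeding, age at reproductive maturity, asexual reproduction, growth
#' rate, calcification, chemical defenses and mobility. Traits whose codes
#' are numbered scales (longevity, height, width, age at maturity, growth
#' rate, solitary--colonial) are declared ordinal; lettered codes are
#' nominal; yes/no traits are binary. Every trait carries a 2--4 category
#' coarse map for sensitivity analyses.
#'
#' @return a `trait_schema` with 15 traits and 73 categories.
#' @export
benthic_schema <- function() {
  read_trait_schema(system.file("extdata", "benthic_schema.yaml",
                                package = "fespace", mustWork = TRUE))
}

#' Derive the coarse schema implied by the coarse maps
#'
#' @param schema a `trait_schema` in which every trait has a `coarse_map`.
#' @return a `trait_schema` over the coarse categories (order of first
#'   appearance along the fine category order, preserving ordinal order).
#' @export
coarse_schema <- function(schema) {
  trait_schema(lapply(unname(schema), function(t) {
    if (is.null(t$coarse_map))
      stop("trait '", t$name, "' has no coarse_map")
    cats <- unique(unname(t$coarse_map))
    kind <- if (t$kind == "binary" && length(cats) != 2L) "nominal" else t$kind
    if (kind == "binary" && length(cats) != 2L) kind <- "nominal"
    if (length(cats) == 1L) kind <- "nominal"
    trait_def(t$name, kind, cats)
  }))
}
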