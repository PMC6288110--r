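#' Gower distance among species or functional entities
#'
#' Mixed-type Gower dissimilarity with equal trait weights: the distance
#' between two trait vectors is the unweighted mean over traits of the
#' per-trait dissimilarity. Nominal and binary traits contribute 0 when the
#' codes are equal and 1 otherwise. Ordinal traits contribute a
#' range-scaled rank difference, with three conventions selectable via
#' `ordinal`:
#'
#' * `"rank"` (default): ranks are the positions of the categories in the
#'   schema's declared order; the difference is divided by the range of
#'   ranks *observed in the table*. A trait with a single observed category
#'   contributes 0 (degenerate range).
#' * `"podani"`: Podani's tied-rank correction; values are ranked across
#'   the table's rows with ties averaged, differences are shrunk by the tie
#'   sizes and scaled by the tie-corrected observed range.
#' * `"nominal"`: ordinal traits are treated as plain nominal codes.
#'
#' @param table a validated trait table (species rows, or the `fe_table` of
#'   an [build_functional_entities()] partition).
#' @param schema the `trait_schema`.
#' @param ordinal ordinal-trait convention, see above.
#' @return a [stats::dist] object labelled by the table's identifiers, with
#'   entries in `[0, 1]`.
#' @export
gower_dist <- function(table, schema, ordinal = c("rank", "nominal", "podani")) {
  ordinal <- match.arg(ordinal)
  table <- validate_trait_table(table, schema)
  n <- nrow(table)
  if (n < 2L) stop("need at least two entities for a distance matrix")
  acc <- matrix(0, n, n)
  for (tr in names(schema)) {
    def <- schema[[tr]]
    v <- table[[tr]]
    kind <- def$kind
    if (kind == "ordinal" && ordinal == "nominal") kind <- "nominal"
    if (kind == "ordinal" && ordinal == "podani") {
      r <- rank(match(v, def$categories))  # tied ranks over rows
      tie <- table(v)[v]                   # tie group size per row
      rng_max <- max(r); rng_min <- min(r)
      t_max <- tie[which.max(r)]; t_min <- tie[which.min(r)]
      denom <- (rng_max - (t_max - 1) / 2) - (rng_min + (t_min - 1) / 2)
      if (denom <= 0) next
      dr <- abs(outer(r, r, "-")) - outer((tie - 1) / 2, (tie - 1) / 2, "+")
      dr[outer(v, v, "==")] <- 0
      dr <- pmax(dr, 0) / denom
      acc <- acc + dr
    } else if (kind == "ordinal") {
      r <- match(v, def$categories)
      rng <- max(r) - min(r)               # range observed in the table
      if (rng == 0) next                   # degenerate: contributes 0
      acc <- acc + abs(outer(r, r, "-")) / rng
    } else {
      acc <- acc + (outer(v, v, "!=") * 1)
    }
  }
  d <- acc / length(schema)
  rownames(d) <- colnames(d) <- table$species
  stats::as.dist(d)
}
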