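# small in-code fixtures shared across the suite

toy_schema <- function() trait_schema(list(
  trait_def("color", "nominal", c("red", "green", "blue"),
            coarse_map = c(red = "warm", green = "cool", blue = "cool")),
  trait_def("size", "ordinal", as.character(1:4),
            coarse_map = c("1" = "small", "2" = "small",
                           "3" = "large", "4" = "large")),
  trait_def("armed", "binary", c("n", "y"),
            coarse_map = c(n = "n", y = "y"))))

toy_table <- function() data.frame(
  species = c("sp1", "sp2", "sp3", "sp4", "sp5"),
  color = c("red", "red", "green", "blue", "red"),
  size = c("1", "1", "3", "4", "2"),
  armed = c("n", "n", "y", "y", "n"),
  stringsAsFactors = FALSE)

# k all-nominal traits with categories a..e
nominal_schema <- function(k = 15L) trait_schema(lapply(seq_len(k), function(i)
  trait_def(paste0("t", i), "nominal", letters[1:5])))

# trait table whose rows are given trait vectors (matrix: species x traits)
table_from_matrix <- function(m, schema) {
  df <- data.frame(species = sprintf("sp%02d", seq_len(nrow(m))),
                   as.data.frame(m, stringsAsFactors = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("species", names(schema))
  validate_trait_table(df, schema)
}

# minimal functional_space wrapper around raw coordinates
space_from_coords <- function(coords) {
  if (is.null(rownames(coords)))
    rownames(coords) <- sprintf("FE%03d", seq_len(nrow(coords)))
  structure(list(labels = rownames(coords), coords = coords,
                 eigenvalues = NULL, n_axes = ncol(coords), msd = NA_real_,
                 negative_mass = 0, partition = NULL, config = list()),
            class = "functional_space")
}

# one-zone assemblage from named covers
assemblage_from_covers <- function(covers, zone = "ambient") {
  covers <- covers[covers > 0]
  structure(list(zone = zone, mean_cover = covers[order(names(covers))],
                 species_present = sort(names(covers)), n_quadrats = 1L),
            class = "zone_assemblage")
}
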