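Package: fespace
Title: Functional Entities, Trait Spaces and Diversity Along Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Trait-based functional diversity analysis for benthic community
    surveys along environmental gradients. Builds functional entities (unique
    combinations of categorical trait values), embeds them in a Euclidean
    functional space via Gower distances and principal coordinates analysis,
    and quantifies convex-hull functional richness, hull-based functional
    beta-diversity partitioned into turnover and nestedness-resultant
    components (Jaccard family), null models of random species-to-entity
    assignment, and neighbourhood-based functional redundancy and
    vulnerability. Includes a seeded synthetic-community generator emulating
    trait-targeted environmental filtering, and a pipeline runner with
    machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
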