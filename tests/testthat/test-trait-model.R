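test_that("trait tables validate against the schema with informative errors", {
  sch <- toy_schema()
  tab <- validate_trait_table(toy_table(), sch)
  expect_equal(names(tab), c("species", "color", "size", "armed"))
  expect_equal(nrow(tab), 5L)

  bad <- toy_table(); bad$color[2] <- "z"
  expect_error(validate_trait_table(bad, sch), "sp2.*'z'|'z'.*sp2")
  dup <- rbind(toy_table(), toy_table()[1, ])
  expect_error(validate_trait_table(dup, sch), "duplicated species")
  expect_error(validate_trait_table(toy_table()[, -2], sch), "missing trait")
  na <- toy_table(); na$size[3] <- NA
  expect_error(validate_trait_table(na, sch), "missing value")
})

test_that("trait tables survive a write/read round trip exactly", {
  sch <- toy_schema()
  tab <- validate_trait_table(toy_table(), sch)
  for (ext in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_trait_table(tab, path)
    expect_identical(read_trait_table(path, sch), tab)
  }
})

test_that("schemas survive a YAML round trip including coarse maps", {
  sch <- toy_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trait_schema(sch, path)
  back <- read_trait_schema(path)
  expect_equal(names(back), names(sch))
  for (tr in names(sch)) {
    expect_identical(back[[tr]]$categories, sch[[tr]]$categories)
    expect_identical(back[[tr]]$kind, sch[[tr]]$kind)
    expect_identical(back[[tr]]$coarse_map, sch[[tr]]$coarse_map)
  }
})

test_that("the bundled benthic schema declares 15 traits and 73 categories", {
  sch <- benthic_schema()
  expect_length(sch, 15L)
  expect_equal(n_categories(sch), 73L)
  # every trait carries a total 2-4 category coarse map
  for (t in sch) {
    expect_false(is.null(t$coarse_map))
    expect_setequal(names(t$coarse_map), t$categories)
    expect_gte(length(unique(t$coarse_map)), 2L)
    expect_lte(length(unique(t$coarse_map)), 4L)
  }
})

test_that("functional entities are the classes of exact trait-vector equality", {
  sch <- toy_schema()
  # all distinct -> all singletons
  tab <- toy_table(); tab$size <- as.character(1:5 %% 4 + 1)
  tab$color <- c("red", "green", "blue", "red", "green")
  p <- build_functional_entities(tab, sch)
  expect_equal(n_fe(p), 5L)
  expect_true(all(lengths(fe_members(p)) == 1L))

  # all identical -> one FE with every species
  tab2 <- toy_table()
  for (tr in names(sch)) tab2[[tr]] <- tab2[[tr]][1]
  p2 <- build_functional_entities(tab2, sch)
  expect_equal(n_fe(p2), 1L)
  expect_setequal(p2$entities[[1]]$members, tab2$species)

  # mixed: sp1/sp2 share a vector in toy_table
  p3 <- build_functional_entities(toy_table(), sch)
  expect_equal(n_fe(p3), 4L)
  expect_equal(unname(p3$species_to_fe["sp1"]), unname(p3$species_to_fe["sp2"]))
})

test_that("FE identifiers are deterministic under row permutation", {
  sch <- toy_schema()
  tab <- toy_table()
  p1 <- build_functional_entities(tab, sch)
  p2 <- build_functional_entities(tab[sample(nrow(tab)), ], sch)
  expect_identical(p1$fe_table, p2$fe_table)
  expect_identical(p1$species_to_fe[sort(names(p1$species_to_fe))],
                   p2$species_to_fe[sort(names(p2$species_to_fe))])
})

test_that("coarsening merges categories and never splits entities", {
  sch <- toy_schema()
  tab <- validate_trait_table(toy_table(), sch)

  # identity coarse map leaves the table and FE count unchanged
  idsch <- trait_schema(lapply(unname(sch), function(t)
    trait_def(t$name, t$kind, t$categories,
              coarse_map = setNames(t$categories, t$categories))))
  idtab <- coarsen_traits(tab, idsch)
  expect_identical(idtab, tab)
  expect_equal(n_fe(build_functional_entities(idtab, coarse_schema(idsch))),
               n_fe(build_functional_entities(tab, sch)))

  # sp4 (blue,4,y) and sp3 (green,3,y) merge under the toy coarse map
  ctab <- coarsen_traits(tab, sch)
  cp <- build_functional_entities(ctab, coarse_schema(sch))
  expect_equal(unname(cp$species_to_fe["sp3"]), unname(cp$species_to_fe["sp4"]))

  # a trait without a coarse map is an error
  nosch <- trait_schema(list(trait_def("color", "nominal", c("red", "blue"))))
  notab <- data.frame(species = "s1", color = "red")
  expect_error(coarsen_traits(notab, nosch), "coarse_map")
})

test_that("FE count is non-increasing under coarsening for random pools", {
  sch <- benthic_schema()
  csch <- coarse_schema(sch)
  set.seed(71)
  for (i in 1:5) {
    pool <- generate_pool(40, sch, collapse_rate = 0.1, mutation_rate = 0.4)
    fine <- n_fe(build_functional_entities(pool, sch))
    coarse <- n_fe(build_functional_entities(coarsen_traits(pool, sch), csch))
    expect_lte(coarse, fine)
  }
})
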