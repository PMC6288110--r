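test_that("pool generation controls collapse and is seed-deterministic", {
  sch <- benthic_schema()
  # uniform per-trait draws: vector collisions have negligible probability,
  # so the FE count is exactly the species count minus forced duplicates
  set.seed(71)
  p0 <- generate_pool(30, sch, collapse_rate = 0, n_archetypes = 0)
  expect_equal(n_fe(build_functional_entities(p0, sch)), 30L)

  set.seed(72)
  a <- generate_pool(40, sch, collapse_rate = 0.1, n_archetypes = 0)
  set.seed(72)
  b <- generate_pool(40, sch, collapse_rate = 0.1, n_archetypes = 0)
  expect_identical(a, b)
  expect_equal(n_fe(build_functional_entities(a, sch)), 36L)
  expect_error(generate_pool(0, sch), "positive")
})

test_that("gradient surveys honour filtering rules and detection floors", {
  sch <- benthic_schema()
  set.seed(73)
  pool <- generate_pool(40, sch, mutation_rate = 0.3)
  # no filtering, equal concentration: all zones share the pool species
  open_specs <- list(ambient = filter_spec("ambient"),
                     low = filter_spec("low"),
                     extreme_low = filter_spec("extreme_low"))
  sv <- generate_gradient_surveys(pool, open_specs)
  asm <- aggregate_zones(sv)
  for (a in asm) expect_setequal(a$species_present, pool$species)
  expect_true(all(sv$cover >= 0.01))
  expect_equal(length(unique(sv$quadrat_id)), 72L)

  # probability-1 removal of a category empties it from the zone
  hit <- pool$calcification %in% c("c", "e", "f")
  expect_true(any(hit) && !all(hit))  # seed gives a mixed pool
  harsh <- list(extreme_low = filter_spec(
    "extreme_low",
    data.frame(trait = "calcification", category = c("c", "e", "f"),
               prob = 1)))
  sv2 <- generate_gradient_surveys(pool, harsh)
  present <- aggregate_zone(sv2, "extreme_low")$species_present
  expect_length(intersect(present, pool$species[hit]), 0L)

  # filtering everything is an error
  allrules <- do.call(rbind, lapply(names(sch), function(tr)
    data.frame(trait = tr, category = sch[[tr]]$categories, prob = 1)))
  expect_error(
    generate_gradient_surveys(pool, list(x = filter_spec("low", allrules))),
    "zero species")
})

test_that("target richness steers zone species counts exactly", {
  sch <- benthic_schema()
  set.seed(74)
  pool <- generate_pool(72, sch, collapse_rate = 0.06)
  sv <- generate_gradient_surveys(pool, gradient_filter_specs())
  asm <- aggregate_zones(sv)
  expect_equal(vapply(asm, function(a) length(a$species_present), 0L),
               c(ambient = 55L, low = 45L, extreme_low = 22L))
})

test_that("lower Dirichlet concentration increases cover inequality", {
  gini <- function(x) {
    x <- sort(x)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  sch <- benthic_schema()
  set.seed(75)
  pool <- generate_pool(40, sch)
  specs <- list(ambient = filter_spec("ambient", concentration = 5),
                low = filter_spec("low", concentration = 0.5),
                extreme_low = filter_spec("extreme_low", concentration = 0.1))
  sv <- generate_gradient_surveys(pool, specs)
  asm <- aggregate_zones(sv)
  p <- build_functional_entities(pool, sch)
  g <- vapply(asm, function(a) gini(fe_abundance_distribution(a, p)), 0)
  expect_lt(g[["ambient"]], g[["low"]])
  expect_lt(g[["low"]], g[["extreme_low"]])
})

test_that("the deterministic fixture reproduces the planted survey structure", {
  fx <- benthic_gradient_fixture()
  expect_identical(fx$traits, benthic_gradient_fixture()$traits)
  expect_identical(fx$surveys, benthic_gradient_fixture()$surveys)

  expect_equal(nrow(fx$traits), 72L)
  part <- build_functional_entities(fx$traits, fx$schema)
  expect_equal(n_fe(part), 68L)
  sizes <- lengths(fe_members(part))
  expect_equal(sum(sizes == 1L), 66L)  # two FEs hold three species each

  asm <- aggregate_zones(fx$surveys)
  expect_equal(vapply(asm, function(a) length(a$species_present), 0L),
               c(ambient = 55L, low = 45L, extreme_low = 22L))
  expect_equal(vapply(asm, function(a) length(occupied_fes(a, part)), 0L),
               c(ambient = 51L, low = 42L, extreme_low = 21L))
  # the zone sets realised in the surveys are the planted ones
  for (z in names(asm))
    expect_setequal(asm[[z]]$species_present, fx$zone_species[[z]])

  # extreme-low zone: pure photosynthetic autotrophy, no calcification
  en <- trait_category_abundance(asm$extreme_low, fx$traits,
                                 "energetic_resource", fx$schema)
  expect_equal(unname(en["1"]), 100)
  ca <- trait_category_abundance(asm$extreme_low, fx$traits,
                                 "calcification", fx$schema)
  expect_equal(unname(ca["a"]), 100)

  # cover concentrates into few FEs in the extreme-low zone
  top3 <- function(a) {
    fa <- sort(fe_abundance_distribution(a, part), decreasing = TRUE)
    sum(fa[1:3])
  }
  expect_gt(top3(asm$extreme_low), top3(asm$ambient))
  expect_gt(top3(asm$extreme_low), 50)
})

test_that("quadrat covers are plausible percent-cover draws", {
  fx <- benthic_gradient_fixture()
  sv <- fx$surveys
  expect_true(all(sv$cover > 0))
  totals <- tapply(sv$cover, sv$quadrat_id, sum)
  expect_true(all(totals > 20 & totals < 200))
  expect_equal(length(unique(sv$quadrat_id)), 72L)
  expect_setequal(unique(sv$site), c("north", "south"))
})
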