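make_surveys <- function() {
  data.frame(
    quadrat_id = c("q1", "q1", "q2", "q2", "q3"),
    site = c("north", "north", "south", "south", "north"),
    zone = c("ambient", "ambient", "ambient", "ambient", "low"),
    species = c("a", "b", "a", "c", "a"),
    cover = c(10, 4, 30, 2, 8),
    stringsAsFactors = FALSE)
}

test_that("grid counts convert to per-cent cover", {
  expect_equal(grid_to_percent_cover(0), 0)
  expect_equal(grid_to_percent_cover(25), 100)
  expect_equal(grid_to_percent_cover(5), 20)
  expect_equal(grid_to_percent_cover(3, 10), 30)
  expect_error(grid_to_percent_cover(26), "exceeds")
  expect_error(grid_to_percent_cover(-1), "negative")
})

test_that("zone aggregation averages covers over all quadrats of the zone", {
  sv <- make_surveys()
  amb <- aggregate_zone(sv, "ambient")
  # species a: (10 + 30)/2; b: 4/2; c: 2/2
  expect_equal(unname(amb$mean_cover[c("a", "b", "c")]), c(20, 2, 1))
  expect_equal(amb$n_quadrats, 2L)
  expect_setequal(amb$species_present, c("a", "b", "c"))

  low <- aggregate_zone(sv, "low")  # single quadrat = that quadrat
  expect_equal(unname(low$mean_cover["a"]), 8)
  expect_error(aggregate_zone(sv, "extreme_low"), "no quadrats")

  # permutation invariance in row order
  perm <- sv[sample(nrow(sv)), ]
  expect_equal(aggregate_zone(perm, "ambient"), amb)
})

test_that("cover tables round trip in long and wide form", {
  sv <- validate_surveys(make_surveys())
  long_path <- withr::local_tempfile(fileext = ".csv")
  write_cover_long(sv, long_path)
  back <- read_cover_long(long_path)
  expect_equal(back[order(back$quadrat_id, back$species), ],
               sv[order(sv$quadrat_id, sv$species), ],
               ignore_attr = TRUE)

  # wide + sidecar
  wide <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("quadrat_id,a,b,c", "q1,10,4,0", "q2,30,0,2"), wide)
  writeLines(c("quadrat_id,site,zone", "q1,north,ambient", "q2,south,ambient"),
             meta)
  w <- read_cover_wide(wide, meta)
  expect_equal(aggregate_zone(w, "ambient")$mean_cover,
               aggregate_zone(sv, "ambient")$mean_cover)
})

test_that("pool percentages round to the printed integers", {
  expect_identical(pool_percentage(72, 72), 100L)
  expect_identical(pool_percentage(0, 72), 0L)
  expect_error(pool_percentage(3, 0), "positive")
  expect_error(pool_percentage(5, 4), "zone count")
})

test_that("trait-category abundance is cover-weighted and sums to 100", {
  sch <- toy_schema()
  tab <- toy_table()
  # all species share one category -> 100% on it
  a1 <- assemblage_from_covers(c(sp1 = 5, sp2 = 15))
  ab <- trait_category_abundance(a1, tab, "color", sch)
  expect_equal(unname(ab["red"]), 100)
  expect_equal(sum(ab), 100)

  # two equal-cover species in different categories -> 50/50
  a2 <- assemblage_from_covers(c(sp1 = 7, sp3 = 7))
  ab2 <- trait_category_abundance(a2, tab, "color", sch)
  expect_equal(unname(ab2[c("red", "green")]), c(50, 50))

  # species missing from the table is an error naming it
  a3 <- assemblage_from_covers(c(ghost = 3))
  expect_error(trait_category_abundance(a3, tab, "color", sch), "ghost")

  # sums to 100 for every trait of a larger random assemblage
  set.seed(4)
  fx <- benthic_gradient_fixture()
  asm <- aggregate_zones(fx$surveys)
  for (tr in names(fx$schema))
    expect_equal(sum(trait_category_abundance(asm$low, fx$traits, tr,
                                              fx$schema)), 100)
})

test_that("FE abundance distribution normalizes member covers to 100%", {
  sch <- toy_schema()
  p <- build_functional_entities(toy_table(), sch)
  # sp1+sp2 share an FE: covers 30 and 10 against sp3 at 10 -> 80/20
  a <- assemblage_from_covers(c(sp1 = 30, sp2 = 10, sp3 = 10))
  fa <- fe_abundance_distribution(a, p)
  expect_equal(sum(fa), 100)
  expect_equal(unname(fa[p$species_to_fe[["sp1"]]]), 80)
  expect_equal(unname(fa[p$species_to_fe[["sp3"]]]), 20)

  # invariant under uniform rescaling of covers
  a2 <- assemblage_from_covers(c(sp1 = 3, sp2 = 1, sp3 = 1))
  expect_equal(fe_abundance_distribution(a2, p), fa)

  # absent FEs excluded unless dense
  expect_false(p$species_to_fe[["sp4"]] %in% names(fa))
  dense <- fe_abundance_distribution(a, p, dense = TRUE)
  expect_equal(unname(dense[p$species_to_fe[["sp4"]]]), 0)
  expect_length(dense, n_fe(p))
})
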