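# a partition mapping each species directly to its own or a shared FE
manual_partition <- function(species_to_fe, coords) {
  fe_ids <- sort(unique(unname(species_to_fe)))
  entities <- lapply(fe_ids, function(id)
    list(fe_id = id, trait_vector = character(0),
         members = sort(names(species_to_fe)[species_to_fe == id])))
  structure(list(entities = entities, species_to_fe = species_to_fe,
                 fe_table = NULL, traits = character(0)),
            class = "fe_partition")
}

test_that("isolated singleton FEs are fully vulnerable", {
  coords <- diag(4) * 10          # 4 FEs, mutually far apart
  rownames(coords) <- paste0("FE", 1:4)
  sp <- space_from_coords(coords)
  s2f <- setNames(paste0("FE", 1:4), paste0("sp", 1:4))
  part <- manual_partition(s2f, coords)
  asm <- assemblage_from_covers(setNames(rep(5, 4), paste0("sp", 1:4)))
  prof <- redundancy_profile(sp, part, asm, k_frac = 0.01)
  expect_true(all(prof$per_fe$n_species_within == 1L))
  expect_equal(vulnerability(prof), 1)
  expect_equal(mean_species_per_fe(prof, "radius"), 1)
})

test_that("coincident FEs pool their member species within the radius", {
  coords <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(10, 0, 0, 0))
  rownames(coords) <- paste0("FE", 1:3)
  sp <- space_from_coords(coords)
  s2f <- setNames(c("FE1", "FE1", "FE2", "FE2", "FE2", "FE3"),
                  paste0("sp", 1:6))
  part <- manual_partition(s2f, coords)
  asm <- assemblage_from_covers(setNames(c(10, 10, 5, 5, 5, 30),
                                         paste0("sp", 1:6)))
  prof <- redundancy_profile(sp, part, asm, k_frac = 0.01)
  per <- prof$per_fe
  # FE1 (2 members) and FE2 (3 members) coincide: both report 5 species
  expect_equal(per$n_species_within[per$fe_id == "FE1"], 5L)
  expect_equal(per$n_species_within[per$fe_id == "FE2"], 5L)
  expect_equal(per$n_species_within[per$fe_id == "FE3"], 1L)
  expect_equal(vulnerability(prof), 1 / 3)
  # abundance within radius: (10+10+5+5+5)/65 for the coincident pair
  expect_equal(per$abundance_within[per$fe_id == "FE1"], 100 * 35 / 65)
})

test_that("redundancy is monotone in the radius fraction", {
  set.seed(61)
  fx <- benthic_gradient_fixture()
  sp <- build_space(fx$traits, fx$schema)
  asm <- aggregate_zones(fx$surveys)
  fracs <- c(0.005, 0.01, 0.05, 0.2)
  profs <- lapply(fracs, function(k)
    redundancy_profile(sp, sp$partition, asm$ambient, k_frac = k))
  counts <- vapply(profs, function(p) p$per_fe$n_species_within,
                   integer(nrow(profs[[1]]$per_fe)))
  expect_true(all(apply(counts, 1, function(x) all(diff(x) >= 0))))
  vul <- vapply(profs, vulnerability, 0)
  expect_true(all(diff(vul) <= 0))
  # each FE carries at least its own cover
  own <- profs[[1]]
  expect_true(all(own$per_fe$abundance_within > 0))
})

test_that("neighbourhood radii from 0.5% to 5% give consistent profiles", {
  set.seed(62)
  fx <- benthic_gradient_fixture()
  sp <- build_space(fx$traits, fx$schema)
  asm <- aggregate_zones(fx$surveys)
  base <- redundancy_profile(sp, sp$partition, asm$extreme_low, k_frac = 0.01)
  for (k in c(0.005, 0.05)) {
    alt <- redundancy_profile(sp, sp$partition, asm$extreme_low, k_frac = k)
    expect_gt(cor(base$per_fe$abundance_within, alt$per_fe$abundance_within,
                  method = "spearman"), 0.8)
  }
})

test_that("mean species per FE distinguishes naive and radius modes", {
  coords <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(9, 0, 0, 0), c(0, 9, 0, 0))
  rownames(coords) <- paste0("FE", 1:4)
  sp <- space_from_coords(coords)
  s2f <- setNames(c("FE1", "FE2", "FE3", "FE4", "FE1", "FE1", "FE2", "FE2",
                    "FE3", "FE4"), paste0("sp", 1:10))
  part <- manual_partition(s2f, coords)
  expect_equal(mean_species_per_fe(part, "naive"), 10 / 4)
  asm <- assemblage_from_covers(setNames(rep(1, 10), paste0("sp", 1:10)))
  prof <- redundancy_profile(sp, part, asm, k_frac = 0.01)
  # FE1/FE2 co-located: their neighbourhoods hold 3+3 = 6 species each
  expect_equal(mean_species_per_fe(prof, "radius"), mean(c(6, 6, 2, 2)))
  # co-location makes the radius mean exceed the naive mean
  expect_gt(mean_species_per_fe(prof, "radius"),
            mean_species_per_fe(part, "naive"))
})
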