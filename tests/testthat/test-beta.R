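test_that("Jaccard partition reproduces worked set examples", {
  # {1,2,3} vs {2,3,4}: a=2, b=1, c=1
  part <- jaccard_partition(2, 1, 1)
  expect_equal(unname(part), c(0.5, 0.5, 0))
  # identical sets: zero dissimilarity throughout
  expect_equal(unname(jaccard_partition(3, 0, 0)), c(0, 0, 0))
  # strict nesting: turnover 0, nestedness = total
  nest <- jaccard_partition(4, 3, 0)
  expect_equal(nest[["turnover"]], 0)
  expect_equal(nest[["nestedness"]], nest[["total"]])
  expect_error(jaccard_partition(0, 0, 0), "zero")
  expect_error(jaccard_partition(-1, 1, 1), "non-negative")
})

test_that("taxonomic beta-diversity partitions presence/absence correctly", {
  A <- assemblage_from_covers(c(a = 1, b = 1, c = 1))
  B <- assemblage_from_covers(c(b = 1, c = 1, d = 1), zone = "low")
  tb <- taxonomic_beta(A, B)
  expect_equal(tb$total, 0.5)
  expect_equal(tb$turnover, 0.5)
  expect_equal(tb$nestedness, 0)
  expect_equal(taxonomic_beta(A, A)$total, 0)
  D <- assemblage_from_covers(c(x = 1, y = 1), zone = "extreme_low")
  expect_equal(taxonomic_beta(A, D)$total, 1)
  # symmetry
  ba <- taxonomic_beta(B, A)
  expect_equal(ba$total, tb$total)
  expect_equal(ba$turnover, tb$turnover)
  expect_equal(c(ba$b, ba$c), c(tb$c, tb$b))
})

test_that("hull intersections match analytic overlaps", {
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  off <- sq; off[, 1] <- off[, 1] + 0.5
  expect_equal(hull_intersection_volume(sq, off)$volume, 0.5,
               tolerance = 1e-9)
  expect_equal(hull_intersection_volume(sq, sq)$volume, 1, tolerance = 1e-9)
  expect_equal(hull_intersection_volume(sq, sq + 10)$volume, 0)
  # separated simplices in 4D
  s <- rbind(rep(0, 4), diag(4))
  expect_equal(hull_intersection_volume(s, s + 5)$volume, 0)
  # self-intersection equals own volume for a random 4D cloud
  set.seed(41)
  p <- matrix(rnorm(30 * 4), ncol = 4)
  expect_equal(hull_intersection_volume(p, p)$volume,
               convex_hull_volume(p)$volume, tolerance = 1e-8)
  expect_error(hull_intersection_volume(matrix(rnorm(8), 2, 4), p),
               "degenerate")
})

test_that("exact and Monte-Carlo intersections agree on random hull pairs", {
  set.seed(42)
  for (i in 1:4) {
    a <- matrix(rnorm(25 * 4), ncol = 4)
    b <- matrix(rnorm(25 * 4), ncol = 4) * 0.8 + 0.4
    ex <- hull_intersection_volume(a, b, method = "exact")
    mc <- hull_intersection_volume(a, b, method = "monte_carlo",
                                   n_samples = 2e5)
    expect_equal(ex$method, "exact")
    expect_lt(abs(ex$volume - mc$volume), max(3 * mc$mc_se, 1e-9))
  }
})

test_that("functional beta detects nested hulls as pure nestedness", {
  set.seed(43)
  outer <- matrix(rnorm(30 * 4), ncol = 4)
  inner <- outer[1:15, ] * 0.3          # strictly inside
  coords <- rbind(outer, inner)
  rownames(coords) <- sprintf("FE%03d", 1:45)
  sp <- space_from_coords(coords)
  fesA <- sp$labels[1:30]
  fesB <- sp$labels[31:45]
  fb <- functional_beta(sp, fesA, fesB)
  vA <- convex_hull_volume(outer)$volume
  vB <- convex_hull_volume(inner)$volume
  expect_lt(fb$turnover, 1e-6)
  expect_equal(fb$nestedness, (vA - vB) / vA, tolerance = 1e-6)
  expect_equal(fb$nested_fraction_B, 1, tolerance = 1e-8)
  # identical FE sets: zero functional beta
  same <- functional_beta(sp, fesA, fesA)
  expect_equal(same$total, 0)
  # nested_fraction of inner within outer is 1
  expect_equal(nested_fraction(sp, fesB, fesA), 1, tolerance = 1e-8)
})

test_that("beta components are additive and symmetric on the fixture", {
  fx <- benthic_gradient_fixture()
  sp <- build_space(fx$traits, fx$schema)
  asm <- aggregate_zones(fx$surveys)
  bp <- beta_pairs(sp, asm)
  expect_equal(nrow(bp), 6L)  # 3 zone pairs x 2 modes
  expect_equal(bp$total, bp$turnover + bp$nestedness, tolerance = 1e-9)
  expect_true(all(bp$total >= 0 & bp$total <= 1))
  expect_true(all(bp$a >= 0 & bp$b >= 0 & bp$c >= 0))
  # symmetry: swap arguments of one functional pair
  f1 <- functional_beta(sp, occupied_fes(asm$ambient, sp$partition),
                        occupied_fes(asm$low, sp$partition))
  f2 <- functional_beta(sp, occupied_fes(asm$low, sp$partition),
                        occupied_fes(asm$ambient, sp$partition))
  expect_equal(f1$total, f2$total, tolerance = 1e-9)
  expect_equal(f1$turnover, f2$turnover, tolerance = 1e-9)
  # shared hypervolume bounded by the smaller hull: a <= min(V_A, V_B)
  fun <- bp[bp$mode == "functional", ]
  expect_true(all(fun$a <= pmin(fun$a + fun$b, fun$a + fun$c) + 1e-12))
})
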