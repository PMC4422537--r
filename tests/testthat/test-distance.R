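test_that("standardized Euclidean distance matches hand calculation", {
  p <- germplasm_panel(
    data.frame(id = c("a", "b"), country = "x", region = "r"),
    cbind(T1 = c(0, 2)), cbind("L1:a" = c(1L, 1L)))
  d <- standardized_euclidean(p)
  # z-scores with n-1 SD: (0-1)/sqrt(2), (2-1)/sqrt(2) -> d = sqrt(2)
  expect_equal(as.numeric(d), sqrt(2))

  # identical trait vectors are at distance zero
  p2 <- germplasm_panel(
    data.frame(id = c("a", "b", "c"), country = "x", region = "r"),
    cbind(T1 = c(1, 1, 5), T2 = c(2, 2, 9)),
    cbind("L1:a" = c(1L, 1L, 1L)))
  m <- as.matrix(standardized_euclidean(p2))
  expect_equal(m["a", "b"], 0)
})

test_that("distance matrices permute with the accessions", {
  sim <- simulate_panel(simulation_config(n_accessions = 20, seed = 8))
  perm <- sample(20)
  for (f in list(function(p, s) standardized_euclidean(p, subset = s),
                 function(p, s) jaccard_distance(p, subset = s),
                 function(p, s) modified_rogers_distance(p, subset = s))) {
    m1 <- as.matrix(f(sim$panel, NULL))
    m2 <- as.matrix(f(sim$panel, perm))
    expect_equal(m2, m1[perm, perm])
  }
})

test_that("missing traits are pairwise-deleted with sqrt(K/K_obs) rescaling", {
  traits <- cbind(T1 = c(0, 2, 1), T2 = c(1, NA, 3))
  p <- germplasm_panel(
    data.frame(id = c("a", "b", "c"), country = "x", region = "r"),
    traits, cbind("L1:a" = c(1L, 1L, 1L)))
  d <- as.matrix(standardized_euclidean(p))
  z <- scale(traits)
  expect_equal(unname(d["a", "b"]),
               unname(sqrt((z[1, 1] - z[2, 1])^2 * 2 / 1)))
  expect_equal(unname(d["a", "c"]),
               unname(sqrt((z[1, 1] - z[3, 1])^2 + (z[1, 2] - z[3, 2])^2)))

  # a pair sharing no descriptor is an error naming the pair
  t2 <- cbind(T1 = c(1, NA, 2), T2 = c(NA, 1, 3))
  p2 <- germplasm_panel(
    data.frame(id = c("a", "b", "c"), country = "x", region = "r"),
    t2, cbind("L1:a" = c(1L, 1L, 1L)))
  expect_error(standardized_euclidean(p2), "a / b")
})

test_that("Jaccard distance counts band matches and mismatches", {
  # identical profiles -> 0; fully disjoint -> 1
  p <- make_band_panel(list(c(1, 1), c(1, 1), c(2, 2)), c(2, 2))
  m <- as.matrix(jaccard_distance(p))
  expect_equal(m["S01", "S02"], 0)
  expect_equal(m["S01", "S03"], 1)

  # a=2, b=1, c=1 -> s = 0.5: profiles over 4 band columns
  bands <- rbind(c(1L, 1L, 1L, 0L), c(1L, 1L, 0L, 1L))
  colnames(bands) <- c("L1:a", "L1:b", "L2:a", "L2:b")
  p2 <- germplasm_panel(
    data.frame(id = c("x", "y"), country = "c", region = "r"),
    cbind(T1 = c(1, 2)), bands)
  expect_equal(as.numeric(jaccard_distance(p2)), 0.5)
})

test_that("Jaccard ignores bands absent in both and unscored loci", {
  # widening a locus with a band nobody carries leaves distances unchanged
  p_narrow <- make_band_panel(list(c(1, 1, 1), c(1, 2, 1)), c(2, 2, 2))
  p_wide <- make_band_panel(list(c(1, 1, 1), c(1, 2, 1)), c(2, 2, 5))
  expect_equal(as.numeric(jaccard_distance(p_wide)),
               as.numeric(jaccard_distance(p_narrow)))

  # a locus unscored in one accession is excluded pairwise
  p0 <- make_band_panel(list(c(1, 1), c(1, 2)), c(2, 2))
  d0 <- as.numeric(jaccard_distance(p0))
  p_na <- make_band_panel(list(c(1, 1, NA), c(1, 2, 2)), c(2, 2, 2))
  expect_equal(as.numeric(jaccard_distance(p_na)), d0)

  expect_error(jaccard_distance(
    make_band_panel(list(c(1, NA), c(NA, 2)), c(2, 2))), "S01 / S02")
})

test_that("Jaccard agrees with vegan's binary Jaccard on complete data", {
  skip_if_not_installed("vegan")
  sim <- simulate_panel(simulation_config(n_accessions = 15, seed = 9))
  mine <- as.matrix(jaccard_distance(sim$panel))
  ref <- as.matrix(vegan::vegdist(sim$panel$bands, method = "jaccard",
                                  binary = TRUE))
  dimnames(ref) <- dimnames(mine)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("Modified Rogers distance evaluates its closed form", {
  # differ at 1 of 2 loci -> sqrt(1/2); at both -> 1; identical -> 0
  p <- make_band_panel(list(c(1, 1), c(1, 2), c(2, 2), c(1, 1)), c(2, 2))
  m <- as.matrix(modified_rogers_distance(p))
  expect_equal(m["S01", "S04"], 0)
  expect_equal(m["S01", "S02"], sqrt(0.5))
  expect_equal(m["S01", "S03"], 1)

  # missing locus: distance over co-scored loci only
  p2 <- make_band_panel(list(c(1, 1, 1), c(1, NA, 2)), c(2, 2, 2))
  expect_equal(as.numeric(modified_rogers_distance(p2)), sqrt(0.5))
})

test_that("distances satisfy metric properties on random panels", {
  sim <- simulate_panel(simulation_config(n_accessions = 25, seed = 10))
  for (f in list(standardized_euclidean, modified_rogers_distance)) {
    m <- as.matrix(f(sim$panel))
    expect_true(all(m >= 0))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    set.seed(1)
    for (rep in 1:500) {
      ijk <- sample(25, 3)
      expect_lte(m[ijk[1], ijk[3]],
                 m[ijk[1], ijk[2]] + m[ijk[2], ijk[3]] + 1e-12)
    }
  }
})

test_that("group dissimilarity applies MR to pooled frequencies", {
  # duplicated groups are at distance zero
  p <- make_band_panel(list(c(1, 1), c(2, 2), c(1, 1), c(2, 2)), c(2, 2))
  g <- c("g1", "g1", "g2", "g2")
  expect_equal(as.numeric(group_dissimilarity(p, g)), 0)

  # opposite monomorphic groups are at distance 1
  p2 <- make_band_panel(list(c(1, 1), c(1, 1), c(2, 2), c(2, 2)), c(2, 2))
  expect_equal(as.numeric(group_dissimilarity(p2, g)), 1)

  # freqs {1,0} vs {0.5,0.5} at one locus -> 0.5
  p3 <- make_band_panel(list(c(1), c(1), c(1), c(2)), 2)
  expect_equal(as.numeric(group_dissimilarity(p3, g)), 0.5)

  expect_error(group_dissimilarity(p3, c("a", "a", "a", "a")), "2 groups")
})
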