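test_that("objective components behave at their extremes", {
  # identical accessions: MR term 0, monomorphic pooled Shannon 0
  p <- make_band_panel(rep(list(c(1, 1)), 6), c(2, 2))
  expect_equal(minicore_objective(p, 1:3), 0)

  # two maximally distinct accessions, full weight on MR -> objective 1
  p2 <- make_band_panel(list(c(1, 1), c(2, 2)), c(2, 2))
  cfg <- minicore_config(weight_mr = 1, weight_shannon = 0)
  expect_equal(minicore_objective(p2, 1:2, cfg), 1)

  expect_error(minicore_objective(p, 1), "at least 2")
})

test_that("objective equals its hand-computed value on a 3-accession panel", {
  p <- make_band_panel(list(c(1, 1), c(1, 2), c(2, 2)), c(2, 2))
  mr <- as.matrix(modified_rogers_distance(p))
  mean_mr <- mean(mr[upper.tri(mr)])
  # per-locus band frequencies: L1 {2/3, 1/3}, L2 {1/3, 2/3}; mean Shannon
  # information index normalized by log of the panel's 4 declared bands
  I_locus <- -(2 / 3 * log(2 / 3) + 1 / 3 * log(1 / 3))
  shan <- I_locus / log(4)
  expect_equal(minicore_objective(p, 1:3),
               0.7 * mean_mr + 0.3 * shan, tolerance = 1e-12)
})

test_that("optimizer finds the exhaustive optimum on small panels", {
  for (s in 1:3) {
    sim <- simulate_panel(simulation_config(n_accessions = 12, n_loci = 4,
                                            seed = 30 + s))
    cfg <- minicore_config(target_fraction = 0.25, steps = 400,
                           n_replicas = 3, seed = s)
    subsets <- utils::combn(12, 3)
    best_exh <- max(apply(subsets, 2, function(ss) {
      minicore_objective(sim$panel, ss, cfg)
    }))
    opt <- build_minicore(sim$panel, cfg)
    expect_equal(opt$selection$objective, best_exh, tolerance = 1e-10)
  }
})

test_that("optimizer beats random subsets of the same size", {
  sim <- simulate_panel(simulation_config(n_accessions = 150, seed = 33))
  cfg <- minicore_config(target_fraction = 0.2, steps = 800, n_replicas = 2,
                         seed = 1)
  opt <- build_minicore(sim$panel, cfg)
  k <- length(opt$selection)
  set.seed(99)
  for (rep in 1:100) {
    rnd <- sample(150, k)
    expect_gte(opt$selection$objective,
               minicore_objective(sim$panel, rnd, cfg) - 1e-12)
  }
})

test_that("best-so-far objective is monotone and budget-monotone", {
  sim <- simulate_panel(simulation_config(n_accessions = 60, seed = 34))
  cfg <- minicore_config(steps = 300, n_replicas = 2, seed = 2)
  opt <- build_minicore(sim$panel, cfg)
  tr <- opt$trace
  for (r in unique(tr$replica)) {
    expect_true(all(diff(tr$best[tr$replica == r]) >= 0))
  }
  small <- build_minicore(sim$panel,
                          minicore_config(steps = 50, n_replicas = 2,
                                          seed = 2))
  expect_gte(opt$selection$objective, small$selection$objective)
  # reproducibility
  again <- build_minicore(sim$panel, cfg)
  expect_identical(opt$selection$indices, again$selection$indices)
})

test_that("zero step budget returns a random subset with a warning", {
  sim <- simulate_panel(simulation_config(n_accessions = 40, seed = 35))
  expect_warning(
    out <- build_minicore(sim$panel, minicore_config(steps = 0, seed = 3)),
    "budget")
  expect_length(out$selection, 8)
})

test_that("cluster-sampling baseline honors per-cluster quotas", {
  sim <- simulate_panel(simulation_config(n_accessions = 200, seed = 36))
  sel <- minicore_by_cluster_sampling(sim$panel, fraction = 0.2, seed = 4,
                                      k = 8)
  sc <- sel$strata_counts
  expect_equal(sum(sc$selected), length(sel))
  expect_true(all(sc$selected ==
                    pmax(1, pmin(sc$size, floor(0.2 * sc$size + 0.5)))))

  # single cluster: plain random draw of 20%
  one <- minicore_by_cluster_sampling(sim$panel, fraction = 0.2, seed = 4,
                                      k = 1)
  expect_length(one, 40)

  full <- minicore_by_cluster_sampling(sim$panel, fraction = 1, seed = 4)
  expect_length(full, 200)
})

test_that("region baseline stratifies by region only", {
  passport <- data.frame(id = sprintf("R%03d", 1:100), country = "x",
                         region = rep(c("r1", "r2"), each = 50),
                         stringsAsFactors = FALSE)
  p <- germplasm_panel(passport, cbind(T1 = rnorm(100)),
                       cbind("L1:a" = rep(1L, 100)))
  sel <- minicore_by_region(p, fraction = 0.2, seed = 5)
  expect_equal(sel$strata_counts$selected, c(10, 10))
  again <- minicore_by_region(p, fraction = 0.2, seed = 5)
  expect_identical(sel$indices, again$indices)
})

test_that("mini-core comparison table is consistent and monotone", {
  sim <- simulate_panel(simulation_config(n_accessions = 100, seed = 37))
  s1 <- selection(sim$panel, 1:30)
  cmp_same <- compare_minicores(sim$panel, list(a = s1, b = s1))
  md <- attr(cmp_same, "mean_differences")
  expect_equal(md$d_alleles, 0)
  expect_equal(md$d_genotypes, 0)

  sub <- selection(sim$panel, 1:15)
  cmp <- compare_minicores(sim$panel, list(big = s1, small = sub))
  expect_true(all(cmp$alleles_small <= cmp$alleles_big))
  expect_true(all(cmp$genotypes_small <= cmp$genotypes_big))
})

test_that("optimizer retains at least the allele richness of the baselines", {
  for (s in 1:3) {
    sim <- simulate_panel(simulation_config(n_accessions = 200, seed = 40 + s))
    cfg <- minicore_config(steps = 600, n_replicas = 2, seed = s)
    opt <- build_minicore(sim$panel, cfg)$selection
    cl <- minicore_by_cluster_sampling(sim$panel, fraction = 0.2, seed = s)
    rg <- minicore_by_region(sim$panel, fraction = 0.2, seed = s)
    cmp <- compare_minicores(sim$panel,
                             list(opt = opt, cluster = cl, region = rg))
    m <- attr(cmp, "means")
    expect_gte(m["alleles_opt"], m["alleles_cluster"])
    expect_gte(m["alleles_opt"], m["alleles_region"])
  }
})
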