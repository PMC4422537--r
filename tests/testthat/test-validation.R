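test_that("median equality test matches its 2x2 closed form", {
  set.seed(50)
  x <- rnorm(40)
  same <- equality_test(x, x)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)

  # complete separation: table (0,50; 50,0) about the pooled median
  sep <- equality_test(1:50, 51:100)
  expect_equal(sep$statistic, 100)
  expect_lt(sep$p.value, 1e-10)

  # all values equal: degenerate, p = 1
  const <- equality_test(rep(2, 10), rep(2, 10))
  expect_true(const$degenerate)
  expect_equal(const$p.value, 1)
})

test_that("homogeneity test matches the contingency chi-square closed form", {
  # identical samples in identical classes
  x <- rep(c(1.5, 2.5, 3.5), times = c(10, 20, 30))
  same <- homogeneity_test(x, x, bin_edges = 1:4)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # 2x3 table {{10,20,30},{30,20,10}}: E = 20 everywhere, chi2 = 20, df = 2
  y <- rep(c(1.5, 2.5, 3.5), times = c(30, 20, 10))
  h <- homogeneity_test(x, y, bin_edges = 1:4)
  expect_equal(h$statistic, 20)
  expect_equal(h$df, 2)
  expect_equal(h$p.value, pchisq(20, 2, lower.tail = FALSE))
  # independent route: stats::chisq.test on the same table
  ref <- suppressWarnings(chisq.test(rbind(c(10, 20, 30), c(30, 20, 10)),
                                     correct = FALSE))
  expect_equal(h$statistic, unname(ref$statistic))
  expect_equal(h$p.value, ref$p.value)

  # disjoint classes: overwhelming heterogeneity
  far <- homogeneity_test(rep(1.1, 30), rep(3.9, 30), bin_edges = 1:4)
  expect_lt(far$p.value, 1e-10)
})

test_that("sparse classes are pooled before testing", {
  # one stray value would give an expected count < 1 in its class
  x <- c(rep(1.5, 50), 3.9)
  y <- rep(1.5, 50)
  h <- homogeneity_test(x, y, bin_edges = 1:4)
  expect_true(h$degenerate || h$df < 2)
  expect_true(h$p.value >= 0 && h$p.value <= 1)
})

test_that("chi-square tests hold their nominal size (quick check)", {
  set.seed(51)
  rej_eq <- rej_hom <- 0
  reps <- 300
  for (i in seq_len(reps)) {
    x <- rnorm(200)
    y <- rnorm(200)
    if (equality_test(x, y)$p.value < 0.05) rej_eq <- rej_eq + 1
    if (homogeneity_test(x, y, n_classes = 10)$p.value < 0.05) {
      rej_hom <- rej_hom + 1
    }
  }
  expect_lt(abs(rej_eq / reps - 0.05), 0.035)
  expect_lt(abs(rej_hom / reps - 0.05), 0.035)
})

test_that("Q-Q KL distance evaluates the plugin formula", {
  set.seed(52)
  x <- rnorm(500)
  same <- qq_kl(x, x)
  expect_equal(same$kl, 0)
  expect_equal(same$quantiles$qx, same$quantiles$qy)
  expect_equal(nrow(same$quantiles), 199)

  # smoothed bin counts (3,1) vs (1,3): KL = 0.5 * ln 3
  two <- qq_kl(c(0, 0.01), c(1, 0.99), quantile_step = 1 / 3, n_bins = 2)
  expect_equal(two$kl, 0.5 * log(3), tolerance = 1e-12)

  # constant samples
  expect_equal(qq_kl(rep(1, 5), rep(1, 5))$kl, 0)
})

test_that("KL is nonnegative, zero iff binned distributions agree, and
           affine-invariant", {
  set.seed(53)
  for (rep in 1:1000) {
    x <- rnorm(30)
    y <- rnorm(30, mean = runif(1, -1, 1))
    kl <- qq_kl(x, y, quantile_step = 0.05)$kl
    expect_gte(kl, 0)
  }
  x <- rnorm(200)
  y <- rexp(200)
  k1 <- qq_kl(x, y)$kl
  k2 <- qq_kl(3 * x - 7, 3 * y - 7)$kl
  expect_equal(k1, k2, tolerance = 1e-10)
  expect_gt(k1, 0)
})

test_that("Mantel r and p behave on self-comparison and match vegan", {
  set.seed(54)
  m1 <- random_dist_matrix(12)
  self <- mantel_test(m1, m1, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p.value, 1 / 100)

  m2 <- random_dist_matrix(12)
  mine <- mantel_test(m1, m2, n_perm = 199, seed = 2)
  expect_gte(mine$p.value, 1 / 200)
  skip_if_not_installed("vegan")
  ref <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 199)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Mantel permutation p converges to the exact enumeration on 4x4", {
  set.seed(55)
  m1 <- random_dist_matrix(4)
  m2 <- random_dist_matrix(4)
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt])
  allp <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  allp <- allp[apply(allp, 1, function(p) length(unique(p)) == 4), ,
               drop = FALSE]
  r_all <- apply(allp, 1, function(p) cor(m1[lt], m2[p, p][lt]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  mc <- mantel_test(m1, m2, n_perm = 9999, seed = 3)
  expect_equal(mc$p.value, p_exact, tolerance = 0.03)
})

test_that("correlation comparison reproduces the Fisher z closed form", {
  sim <- simulate_panel(simulation_config(n_accessions = 60, seed = 56))
  same <- compare_correlations(sim$panel, 1:30, 1:30)
  expect_true(all(same$z == 0))
  expect_true(all(same$p.value == 1))

  # closed form: r_a = 0.5 (n = 103) vs r_b = 0 (n = 103)
  z <- (atanh(0.5) - atanh(0)) / sqrt(1 / 100 + 1 / 100)
  expect_equal(z, 3.8843, tolerance = 1e-4)
  expect_equal(2 * pnorm(-z), 1.027e-4, tolerance = 1e-3)
})

test_that("compare_collections assembles a full report", {
  sim <- simulate_panel(simulation_config(n_accessions = 300, seed = 57))
  core <- build_core(sim$panel, fraction = 0.2, seed = 1)
  rep <- compare_collections(sim$panel, core, mantel_n_perm = 49)
  expect_s3_class(rep, "comparison_report")
  expect_equal(nrow(rep$traits), 8)
  expect_true(all(c("rel_mean_diff_pct", "equality_p", "homogeneity_p",
                    "shannon_ref", "shannon_subset", "qq_kl") %in%
                    names(rep$traits)))
  expect_true(all(rep$traits$equality_p >= 0 & rep$traits$equality_p <= 1))
  expect_true(all(rep$traits$qq_kl >= 0))
  expect_false(is.null(rep$mantel))
  expect_equal(nrow(rep$correlations), choose(8, 2))

  # biased subset: top decile of V400 must fail homogeneity for V400
  top <- order(sim$panel$traits[, "V400"], decreasing = TRUE)[1:30]
  biased <- compare_collections(sim$panel, sort(top), mantel_n_perm = 0)
  expect_lt(biased$traits$homogeneity_p[biased$traits$descriptor == "V400"],
            0.05)

  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_report(rep, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 8)
})

test_that("permutation p-values live on the (1 + k)/(1 + n) grid, never 0", {
  set.seed(58)
  m1 <- random_dist_matrix(10)
  for (i in 1:5) {
    m2 <- random_dist_matrix(10)
    p <- mantel_test(m1, m2, n_perm = 49, seed = i)$p.value
    expect_gt(p, 0)
    expect_equal((p * 50) %% 1, 0, tolerance = 1e-9)
  }
})
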