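#' Median (Brown-Mood) equality test of two samples
#'
#' Pools both samples, counts how many values of each sample fall above
#' the pooled median, and applies the 1-df chi-square test to the
#' resulting 2 x 2 table (no continuity correction). This is the classical
#' nonparametric "equality of two samples" test reported as a
#' `Prob > ChiSq` by the common statistical suites.
#'
#' @param x,y numeric samples with at least 2 non-missing values each
#' @return list with `statistic`, `p.value`, `table` (2 x 2 counts) and
#'   `degenerate` (TRUE when the table carries no information, e.g. all
#'   values equal; then `p.value` is 1)
#' @export
equality_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per sample")
  med <- stats::median(c(x, y))
  tab <- rbind(x = c(above = sum(x > med), not_above = sum(x <= med)),
               y = c(above = sum(y > med), not_above = sum(y <= med)))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    return(list(statistic = 0, p.value = 1, table = tab, degenerate = TRUE))
  }
  n <- sum(tab)
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    prod(rowSums(tab), colSums(tab))
  list(statistic = unname(stat),
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab, degenerate = FALSE)
}

# Pool classes with expected count < 1 into their neighbor (left to right,
# last into the previous) until all expected counts are workable.
pool_sparse_classes <- function(counts) {
  repeat {
    k <- ncol(counts)
    if (k <= 1) break
    exp <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    bad <- which(apply(exp, 2, min) < 1)
    if (!length(bad)) break
    j <- bad[1]
    tgt <- if (j < k) j + 1L else j - 1L
    counts[, tgt] <- counts[, tgt] + counts[, j]
    counts <- counts[, -j, drop = FALSE]
  }
  counts
}

#' Chi-square homogeneity test on shared trait classes
#'
#' Bins both samples into a shared equal-width class system (edges from the
#' reference collection) and tests homogeneity of the two binned
#' distributions with a chi-square test on the 2 x k table. Classes with
#' expected count below 1 are pooled into their neighbor before testing;
#' degrees of freedom are `k' - 1` after pooling.
#'
#' @param x,y numeric samples
#' @param n_classes number of classes when `bin_edges` is not given
#' @param bin_edges shared class boundaries (recommended: from the
#'   reference panel via [trait_bin_edges()]); default: equal-width over
#'   the pooled range
#' @return list with `statistic`, `p.value`, `df`, `table` (2 x k' counts
#'   after pooling) and `degenerate`
#' @export
homogeneity_test <- function(x, y, n_classes = 10, bin_edges = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  if (is.null(bin_edges)) {
    rng <- range(c(x, y))
    if (diff(rng) == 0) {
      return(list(statistic = 0, p.value = 1, df = 0, table = NULL,
                  degenerate = TRUE))
    }
    bin_edges <- seq(rng[1], rng[2], length.out = n_classes + 1)
  }
  nb <- length(bin_edges) - 1
  cx <- tabulate(findInterval(pmin(pmax(x, bin_edges[1]), bin_edges[nb + 1]),
                              bin_edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = nb)
  cy <- tabulate(findInterval(pmin(pmax(y, bin_edges[1]), bin_edges[nb + 1]),
                              bin_edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = nb)
  counts <- rbind(x = cx, y = cy)
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  counts <- pool_sparse_classes(counts)
  if (ncol(counts) < 2) {
    return(list(statistic = 0, p.value = 1, df = 0, table = counts,
                degenerate = TRUE))
  }
  exp <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - exp)^2 / exp)
  df <- ncol(counts) - 1
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df, table = counts, degenerate = FALSE)
}

#' Q-Q quantile comparison with plugin Kullback-Leibler distance
#'
#' Computes the empirical quantiles of both samples on the grid
#' `{step, 2 step, ..., 1 - step}` (linear interpolation between order
#' statistics; `step = 0.005` gives the classical 199-point 0.5% grid).
#' The two quantile vectors are then discretized into shared equal-width
#' bins and the Kullback-Leibler distance `KL(p || q) = sum p log(p / q)`
#' is computed by the plugin estimator on the binned frequencies, with
#' add-one smoothing of the counts (applied to both sides) so empty
#' q-bins are defined.
#'
#' @param x,y nonempty numeric samples (`x` is the reference collection)
#' @param quantile_step grid spacing in (0, 0.5)
#' @param n_bins number of shared discretization bins
#' @return list with `quantiles` (data.frame `prob`, `qx`, `qy`) and `kl`
#' @export
qq_kl <- function(x, y, quantile_step = 0.005, n_bins = 20) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  if (quantile_step <= 0 || quantile_step >= 0.5) {
    stop("quantile_step must be in (0, 0.5)")
  }
  probs <- seq(quantile_step, 1 - quantile_step, by = quantile_step)
  qx <- stats::quantile(x, probs, type = 7, names = FALSE)
  qy <- stats::quantile(y, probs, type = 7, names = FALSE)
  rng <- range(c(qx, qy))
  if (diff(rng) == 0) {
    return(list(quantiles = data.frame(prob = probs, qx = qx, qy = qy),
                kl = 0))
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bx <- tabulate(findInterval(qx, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  by <- tabulate(findInterval(qy, edges, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  p <- (bx + 1) / sum(bx + 1)
  q <- (by + 1) / sum(by + 1)
  kl <- sum(p * log(p / q))
  list(quantiles = data.frame(prob = probs, qx = qx, qy = qy), kl = kl)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the off-diagonal triangles of two distance
#' matrices over the same accessions, with significance from simultaneous
#' row/column permutations of the second matrix:
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)` (one-sided, as the
#' population-genetic suites report it; `alternative = "two.sided"` ranks
#' `|r|`).
#'
#' @param d1,d2 `dist` objects or distance matrices with identical labels
#'   in identical order
#' @param n_perm number of permutations (classically 999)
#' @param seed integer seed
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @return list with `r`, `p.value`, `n_perm`, `flagged` (TRUE when a
#'   triangle has zero variance and `r` is undefined)
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) stop("matrices differ in size")
  l1 <- rownames(m1)
  l2 <- rownames(m2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stop("matrix labels differ")
  }
  if (n_perm < 1) stop("n_perm must be >= 1")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (stats::sd(v1) == 0 || stats::sd(m2[lt]) == 0) {
    return(list(r = NA_real_, p.value = NA_real_, n_perm = n_perm,
                flagged = TRUE))
  }
  r_obs <- stats::cor(v1, m2[lt])
  n <- nrow(m1)
  score <- function(r) if (alternative == "greater") r else abs(r)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      rp <- stats::cor(v1, m2[p, p][lt])
      if (score(rp) >= score(r_obs) - 1e-12) hits <- hits + 1L
    }
    list(r = r_obs, p.value = (1 + hits) / (1 + n_perm),
         n_perm = n_perm, flagged = FALSE)
  })
}

#' Compare trait correlation structure of two subsets
#'
#' For every descriptor pair, Fisher z-transforms each subset's Pearson
#' correlation and tests equality of the two population correlations:
#' `z = (z_a - z_b) / sqrt(1/(n_a - 3) + 1/(n_b - 3))`, two-sided normal
#' p-value. A correlation of exactly +/-1 yields an infinite z and is
#' flagged with p = 0.
#'
#' @param panel a [germplasm_panel]
#' @param subset_a,subset_b [selection]s, ids or indices (>= 4 accessions)
#' @param descriptors codes to include (default: all)
#' @return data.frame with one row per descriptor pair: `r_a`, `r_b`,
#'   `n_a`, `n_b`, `z`, `p.value`, `flagged`
#' @export
compare_correlations <- function(panel, subset_a, subset_b,
                                 descriptors = NULL) {
  ia <- resolve_subset(panel, subset_a)
  ib <- resolve_subset(panel, subset_b)
  if (length(ia) < 4 || length(ib) < 4) stop("need >= 4 accessions per subset")
  if (is.null(descriptors)) descriptors <- panel$descriptors$code
  pairs <- utils::combn(descriptors, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    c1 <- pairs[1, j]
    c2 <- pairs[2, j]
    cc_a <- stats::complete.cases(panel$traits[ia, c(c1, c2)])
    cc_b <- stats::complete.cases(panel$traits[ib, c(c1, c2)])
    na <- sum(cc_a)
    nb <- sum(cc_b)
    ra <- stats::cor(panel$traits[ia[cc_a], c1], panel$traits[ia[cc_a], c2])
    rb <- stats::cor(panel$traits[ib[cc_b], c1], panel$traits[ib[cc_b], c2])
    flag <- abs(ra) >= 1 || abs(rb) >= 1 || na < 4 || nb < 4
    z <- if (flag) Inf else {
      (atanh(ra) - atanh(rb)) / sqrt(1 / (na - 3) + 1 / (nb - 3))
    }
    p <- if (flag) 0 else 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(c1, c2, sep = ":"), r_a = ra, r_b = rb,
               n_a = na, n_b = nb, z = z, p.value = p, flagged = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full subset-versus-collection comparison report
#'
#' Assembles, per descriptor: means and variances of both collections, the
#' relative mean difference (%), the median equality test, the class
#' homogeneity test on the reference class system, the normalized
#' Shannon-Weaver indices and the Q-Q Kullback-Leibler distance. Globally:
#' the Mantel test between the subset's phenotypic (standardized
#' Euclidean) and genotypic (Jaccard) distance matrices, and the Fisher-z
#' comparison of all trait correlations.
#'
#' @param panel the reference [germplasm_panel] (defines class systems)
#' @param subset a [selection], ids or indices
#' @param reference optional second selection to compare against (default:
#'   the whole panel)
#' @param mantel_n_perm permutations for the Mantel test (0 skips it, e.g.
#'   for very small subsets)
#' @param mantel_max_n subsample size cap for the Mantel test (distance
#'   matrices grow quadratically); default 300
#' @param seed seed for the Mantel permutations/subsample
#' @return list of class `comparison_report` with elements `traits`
#'   (per-descriptor data.frame), `correlations`, `mantel`
#' @export
compare_collections <- function(panel, subset, reference = NULL,
                                mantel_n_perm = 199L, mantel_max_n = 300L,
                                seed = 1L) {
  idx <- resolve_subset(panel, subset)
  ref <- resolve_subset(panel, reference)
  if (!length(idx)) stop("subset is empty")
  rows <- lapply(panel$descriptors$code, function(cd) {
    nc <- panel$descriptors$n_classes[match(cd, panel$descriptors$code)]
    edges <- trait_bin_edges(panel, cd, nc)
    xr <- panel$traits[ref, cd]
    xs <- panel$traits[idx, cd]
    eq <- equality_test(xr, xs)
    hom <- homogeneity_test(xr, xs, bin_edges = edges)
    kl <- qq_kl(xr, xs)$kl
    mr <- mean(xr, na.rm = TRUE)
    ms <- mean(xs, na.rm = TRUE)
    data.frame(descriptor = cd,
               mean_ref = mr, mean_subset = ms,
               rel_mean_diff_pct = if (mr != 0) 100 * abs(ms - mr) / abs(mr)
                                   else NA_real_,
               var_ref = stats::var(xr, na.rm = TRUE),
               var_subset = stats::var(xs, na.rm = TRUE),
               equality_p = eq$p.value,
               equality_degenerate = eq$degenerate,
               homogeneity_p = hom$p.value,
               homogeneity_degenerate = hom$degenerate,
               n_classes = nc,
               shannon_ref = trait_shannon_index(panel, cd, nc, edges, ref),
               shannon_subset = trait_shannon_index(panel, cd, nc, edges, idx),
               qq_kl = kl,
               stringsAsFactors = FALSE)
  })
  traits <- do.call(rbind, rows)

  mantel <- NULL
  if (mantel_n_perm > 0 && length(idx) >= 4) {
    midx <- idx
    if (length(midx) > mantel_max_n) {
      midx <- with_seed(seed, sort(sample(midx, mantel_max_n)))
    }
    dp <- standardized_euclidean(panel, subset = midx)
    dg <- jaccard_distance(panel, subset = midx)
    mantel <- mantel_test(dp, dg, n_perm = mantel_n_perm, seed = seed)
  }

  cors <- if (length(idx) >= 4 && length(ref) >= 4) {
    compare_correlations(panel, ref, idx)
  } else NULL

  structure(list(traits = traits, correlations = cors, mantel = mantel),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  print(x$traits[, c("descriptor", "mean_ref", "mean_subset",
                     "rel_mean_diff_pct", "equality_p", "homogeneity_p",
                     "shannon_ref", "shannon_subset", "qq_kl")],
        digits = 4)
  if (!is.null(x$mantel)) {
    cat(sprintf("Mantel (phenotypic vs genotypic): r = %.3f, p = %.4g\n",
                x$mantel$r, x$mantel$p.value))
  }
  invisible(x)
}

#' Write a comparison report as CSV
#'
#' One row per descriptor in the layout of the published whole/core/mini
#' comparison tables, with a trailing comment naming the reference
#' collection used for the class system.
#'
#' @param report a `comparison_report`
#' @param path output CSV
#' @return invisibly, `path`
#' @export
write_comparison_report <- function(report, path) {
  utils::write.csv(report$traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
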