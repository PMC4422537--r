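# round-half-up, used for per-cluster quotas so 0.5 never rounds down
round_half_up <- function(x) floor(x + 0.5)

# Draw round(fraction * size) accessions (min 1) from each cluster.
# `clusters` is a list of integer index vectors; returns sorted indices and
# a per-cluster count table.
sample_within_clusters <- function(clusters, fraction) {
  picked <- integer(0)
  counts <- integer(length(clusters))
  for (i in seq_along(clusters)) {
    mem <- clusters[[i]]
    m <- max(1L, round_half_up(fraction * length(mem)))
    m <- min(m, length(mem))
    take <- if (length(mem) == 1L) mem else sample(mem, m)
    picked <- c(picked, take)
    counts[i] <- length(take)
  }
  list(indices = sort(picked), counts = counts)
}

#' Build a core collection by stratified cluster sampling
#'
#' The construction follows the classical genebank recipe: accessions are
#' stratified by geographic region; within each region they are clustered
#' on the standardized Euclidean distance over the quantitative descriptors
#' (UPGMA, cut into flat clusters); and from every cluster a fixed fraction
#' of accessions is drawn uniformly at random (at least one per nonempty
#' cluster). The union over clusters and regions is the core.
#'
#' A region with a single accession has no distance structure; its
#' accession enters the core with probability `fraction`.
#'
#' @param panel a [germplasm_panel]; every accession must have a region
#' @param fraction sampling fraction in (0, 1); the classical core uses 0.2
#' @param cut_height optional dendrogram cut height (standardized Euclidean
#'   units) defining the within-region clusters
#' @param target_clusters clusters per region when `cut_height` is not
#'   given; either a single integer or the default heuristic
#'   `max(2, ceiling(region_size / 50))`
#' @param seed integer seed; the selection is reproducible from it
#' @param descriptors descriptor codes used for clustering (default: all)
#' @return a [selection] with per-region/per-cluster counts in
#'   `strata_counts`
#' @export
build_core <- function(panel, fraction = 0.2, cut_height = NULL,
                       target_clusters = NULL, seed = 1L,
                       descriptors = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (n_accessions(panel) == 0) stop("empty panel")
  regions <- panel$passport$region
  if (anyNA(regions) || any(!nzchar(regions))) {
    stop("every accession needs a region")
  }
  with_seed(seed, {
    picked <- integer(0)
    strata <- list()
    for (r in unique(regions)) {
      idx <- which(regions == r)
      if (length(idx) == 1L) {
        take <- if (stats::runif(1) < fraction) idx else integer(0)
        picked <- c(picked, take)
        strata[[length(strata) + 1L]] <-
          data.frame(region = r, cluster = 1L, size = 1L,
                     selected = length(take))
        next
      }
      d <- standardized_euclidean(panel, descriptors = descriptors,
                                  subset = idx)
      tree <- upgma(d)
      cl <- if (!is.null(cut_height)) {
        cut_tree(tree, height = cut_height)
      } else {
        k <- if (is.null(target_clusters)) {
          max(2L, ceiling(length(idx) / 50))
        } else target_clusters
        cut_tree(tree, k = min(k, length(idx)))
      }
      clusters <- split(idx, cl)
      sw <- sample_within_clusters(clusters, fraction)
      picked <- c(picked, sw$indices)
      strata[[length(strata) + 1L]] <-
        data.frame(region = r, cluster = seq_along(clusters),
                   size = lengths(clusters), selected = sw$counts)
    }
    selection(panel, sort(picked), method = "stratified_cluster",
              seed = as.integer(seed), fraction = fraction,
              strata_counts = do.call(rbind, strata))
  })
}

#' Check how well a core represents its source collection
#'
#' Thin wrapper around [compare_collections()] comparing the core against
#' the whole panel: per-descriptor relative mean differences, variances,
#' equality and homogeneity test p-values and Shannon-Weaver indices, plus
#' the global Q-Q Kullback-Leibler distances.
#'
#' @param panel the whole-collection [germplasm_panel]
#' @param core a [selection] drawn from it
#' @param ... passed to [compare_collections()]
#' @return a `comparison_report` (see [compare_collections()])
#' @export
validate_core_representativeness <- function(panel, core, ...) {
  if (!length(core$indices)) stop("core selection is empty")
  compare_collections(panel, core, ...)
}
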