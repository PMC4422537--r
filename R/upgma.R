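#' UPGMA (average-linkage) hierarchical clustering
#'
#' Standard unweighted pair-group clustering: at each step the pair of
#' clusters with the smallest average inter-cluster distance is merged at a
#' height equal to that distance, and distances to the merged cluster are
#' the size-weighted averages of its parts. Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels (each cluster labeled by its smallest member label), so the tree
#' does not depend on input order beyond the labels themselves.
#'
#' The result is a genuine `hclust` object, so [stats::cophenetic()],
#' [stats::cutree()] and plotting work on it directly; the cophenetic
#' distance between two leaves equals the merge height of their lowest
#' common ancestor.
#'
#' @param dist a `stats::dist` object or symmetric distance matrix with
#'   labels; must be finite and at least 2 x 2
#' @return an object of class `hclust` (method `"upgma"`)
#' @export
upgma <- function(dist) {
  m <- as.matrix(dist)
  if (nrow(m) < 2) stop("need at least 2 observations")
  if (any(!is.finite(m))) stop("distance matrix contains NA/NaN/Inf")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)

  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node <- -seq_len(n)          # hclust code: negative leaf, positive merge
  minlab <- labels             # smallest member label per cluster
  d <- m
  diag(d) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    dm <- d
    dm[!active, ] <- Inf
    dm[, !active] <- Inf
    dm[lower.tri(dm, diag = TRUE)] <- Inf
    h <- min(dm)
    cand <- which(dm == h, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      key1 <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
      key2 <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
      cand <- cand[order(key1, key2)[1], , drop = FALSE]
    }
    i <- cand[1, 1]
    j <- cand[1, 2]

    merge[step, ] <- sort_merge_pair(node[i], node[j])
    height[step] <- h
    # Lance-Williams average-linkage update, result stored in slot i
    new_d <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- new_d
    d[, i] <- new_d
    d[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    node[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
  }

  hc <- structure(list(merge = merge, height = height,
                       order = hclust_leaf_order(merge),
                       labels = labels, method = "upgma",
                       call = match.call(), dist.method = "unknown"),
                  class = "hclust")
  hc
}

# hclust merge-row convention: singletons (negative, by ascending
# observation index) before earlier merges (positive, ascending)
sort_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) {
    c(max(a, b), min(a, b))  # -1 before -2
  } else {
    c(min(a, b), max(a, b))  # negative before positive; steps ascending
  }
}

hclust_leaf_order <- function(merge) {
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(merge[k, 1]), leaves(merge[k, 2]))
  }
  leaves(nrow(merge))
}

#' Cut a dendrogram into flat clusters
#'
#' Clusters are the connected leaf sets joined strictly below the given
#' height (equivalently, at most `k` clusters). Cluster labels are assigned
#' deterministically: cluster 1 contains the lowest panel index, and so on.
#'
#' @param tree an `hclust` object (e.g. from [upgma()])
#' @param height cut height; merges at height `<= height` are kept
#' @param k alternatively, the desired number of clusters
#' @return integer cluster assignment named by leaf label
#' @export
cut_tree <- function(tree, height = NULL, k = NULL) {
  if (is.null(height) && is.null(k)) stop("give height or k")
  if (!is.null(height) && height < 0) stop("height must be >= 0")
  cl <- if (!is.null(k)) {
    stats::cutree(tree, k = min(k, length(tree$labels)))
  } else {
    stats::cutree(tree, h = height)
  }
  # renumber by first appearance: cluster 1 holds the lowest leaf index
  stats::setNames(match(cl, unique(cl)), tree$labels)
}
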