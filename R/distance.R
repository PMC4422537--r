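#' Standardized Euclidean distance on quantitative descriptors
#'
#' Each descriptor is z-scored (mean 0, SD 1 with `n - 1` denominator) over
#' the analyzed accession set; the distance is the Euclidean distance over
#' descriptors non-missing in both members of a pair, rescaled by
#' `sqrt(K / K_obs)` so pairs with unequal trait coverage stay comparable.
#' Descriptors constant over the analyzed set contribute zero.
#'
#' @param panel a [germplasm_panel]
#' @param descriptors descriptor codes to use (default: all)
#' @param subset optional [selection], ids or indices
#' @return a `stats::dist` object labeled by accession id
#' @export
standardized_euclidean <- function(panel, descriptors = NULL, subset = NULL) {
  idx <- resolve_subset(panel, subset)
  if (length(idx) < 2) stop("need at least 2 accessions")
  if (is.null(descriptors)) descriptors <- panel$descriptors$code
  x <- panel$traits[idx, descriptors, drop = FALSE]
  mu <- colMeans(x, na.rm = TRUE)
  sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1  # constant column -> zero contribution
  z <- sweep(sweep(x, 2, mu, `-`), 2, sd, `/`)
  d <- stats::dist(z)  # dist() rescales pairwise-deleted sums by K/K_obs
  if (anyNA(d)) {
    m <- as.matrix(d)
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1, ]
    stop("no shared non-missing descriptor for pair ",
         panel$ids[idx[bad[1]]], " / ", panel$ids[idx[bad[2]]])
  }
  attr(d, "Labels") <- panel$ids[idx]
  d
}

# Shared scaffolding for band-matrix distances: X = bands with NA -> 0,
# W = per-column validity under locus-level missingness.
band_workspace <- function(panel, idx) {
  bands <- panel$bands[idx, , drop = FALSE]
  lm <- locus_missing(panel)[idx, , drop = FALSE]
  W <- 1 - lm[, match(panel$band_locus, names(panel$loci)), drop = FALSE]
  X <- bands
  X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  storage.mode(W) <- "double"
  X <- X * W  # a partially scored locus counts as unscored throughout
  list(X = X, W = W, lociok = 1 - lm)
}

as_dist_checked <- function(m, labels, pair_err) {
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  if (anyNA(m)) {
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1, ]
    stop(pair_err, ": ", labels[bad[1]], " / ", labels[bad[2]])
  }
  stats::as.dist(m)
}

#' Jaccard distance on dominant band profiles
#'
#' Similarity `s = a / (a + b + c)` over band columns, where `a` counts
#' shared presences and `b`, `c` one-sided presences; distance is `1 - s`.
#' Columns of loci unscored in either accession are excluded pairwise. A
#' pair with co-scored columns but no band present in either profile is
#' assigned distance 0.
#'
#' @inheritParams standardized_euclidean
#' @return a `stats::dist` object labeled by accession id
#' @export
jaccard_distance <- function(panel, subset = NULL) {
  idx <- resolve_subset(panel, subset)
  if (length(idx) < 2) stop("need at least 2 accessions")
  ws <- band_workspace(panel, idx)
  a <- tcrossprod(ws$X)                       # shared presences
  pres_i <- tcrossprod(ws$X, ws$W)            # i's presences valid for j
  shared <- tcrossprod(ws$W)                  # co-scored band columns
  union <- pres_i + t(pres_i) - a             # a + b + c
  s <- ifelse(union > 0, a / union, 1)        # both empty -> identical
  s[shared == 0] <- NA                        # no co-scored bands
  as_dist_checked(1 - s, panel$ids[idx], "no co-scored bands for pair")
}

#' Modified Rogers' distance between accessions
#'
#' With per-locus band indicator vectors `x` (a single band per locus is a
#' unit vector), `MR(i, j) = sqrt(sum((x_i - x_j)^2) / (2 m))` over the `m`
#' loci scored in both accessions. Accessions differing at every co-scored
#' locus are at distance 1.
#'
#' @inheritParams standardized_euclidean
#' @return a `stats::dist` object labeled by accession id
#' @export
modified_rogers_distance <- function(panel, subset = NULL) {
  idx <- resolve_subset(panel, subset)
  if (length(idx) < 2) stop("need at least 2 accessions")
  ws <- band_workspace(panel, idx)
  xy <- tcrossprod(ws$X)
  xw <- tcrossprod(ws$X, ws$W)
  ss <- xw + t(xw) - 2 * xy                  # sum of squared differences
  m <- tcrossprod(ws$lociok)                 # co-scored loci
  d2 <- ifelse(m > 0, ss / (2 * m), NA)
  as_dist_checked(sqrt(pmax(d2, 0)), panel$ids[idx],
                  "no co-scored loci for pair")
}

#' Pooled-frequency Modified Rogers' dissimilarity between groups
#'
#' Groups of accessions (e.g. geographic origins or trait classes) are each
#' pooled into a per-locus allele-frequency table; the between-group
#' distance applies the Modified Rogers formula to the two pooled frequency
#' vectors over loci scored in both groups.
#'
#' @param panel a [germplasm_panel]
#' @param grouping vector of group labels, one per accession (or named by
#'   accession id)
#' @return a `stats::dist` object over group labels
#' @export
group_dissimilarity <- function(panel, grouping) {
  if (!is.null(names(grouping))) {
    grouping <- grouping[panel$ids]
  }
  if (length(grouping) != n_accessions(panel)) {
    stop("grouping must cover every accession")
  }
  if (anyNA(grouping)) stop("grouping has missing labels")
  groups <- unique(as.character(grouping))
  if (length(groups) < 2) stop("need at least 2 groups")
  fts <- lapply(groups, function(g) {
    allele_frequencies(panel, which(grouping == g))
  })
  names(fts) <- groups
  G <- length(groups)
  m <- matrix(0, G, G, dimnames = list(groups, groups))
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      ss <- 0
      nl <- 0
      for (ln in names(panel$loci)) {
        li <- fts[[i]][[ln]]
        lj <- fts[[j]][[ln]]
        if (li$empty || lj$empty) next
        ss <- ss + sum((li$freq - lj$freq)^2)
        nl <- nl + 1
      }
      if (nl == 0) {
        stop("groups ", groups[i], " and ", groups[j],
             " share no scored locus")
      }
      m[i, j] <- m[j, i] <- sqrt(ss / (2 * nl))
    }
  }
  stats::as.dist(m)
}
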