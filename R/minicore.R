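#' Mini-core objective configuration
#'
#' The optimizer maximizes
#' `weight_mr * mean pairwise Modified Rogers' distance +
#'  weight_shannon * normalized Shannon band diversity`
#' over subsets of a fixed target size. The Shannon term is the subset's
#' per-locus Shannon information index averaged over loci and normalized
#' by the log of the total number of bands declared in the panel, so both
#' terms live on `[0, 1]` (a subset of identical accessions scores 0) and
#' the classical 0.7 / 0.3 weighting is meaningful.
#'
#' @param weight_mr weight of the mean Modified Rogers term (default 0.7)
#' @param weight_shannon weight of the pooled Shannon term (default 0.3);
#'   the two weights must be nonnegative and sum to 1
#' @param target_fraction subset size as a fraction of the panel
#'   (default 0.2)
#' @param steps proposal budget per replica
#' @param n_replicas number of independent stochastic searches
#' @param restart_every steps between replica restarts from the global best
#' @param seed integer seed
#' @return list of class `minicore_config`
#' @export
minicore_config <- function(weight_mr = 0.7, weight_shannon = 0.3,
                            target_fraction = 0.2, steps = 2000L,
                            n_replicas = 3L, restart_every = 250L,
                            seed = 1L) {
  if (weight_mr < 0 || weight_shannon < 0) stop("weights must be >= 0")
  if (abs(weight_mr + weight_shannon - 1) > 1e-9) {
    stop("weight_mr + weight_shannon must equal 1")
  }
  if (target_fraction <= 0 || target_fraction >= 1) {
    stop("target_fraction must be in (0, 1)")
  }
  structure(list(weight_mr = weight_mr, weight_shannon = weight_shannon,
                 target_fraction = target_fraction, steps = as.integer(steps),
                 n_replicas = as.integer(n_replicas),
                 restart_every = as.integer(restart_every),
                 seed = as.integer(seed)),
            class = "minicore_config")
}

# Band counts of a subset: one count vector over all band columns,
# counting only scored loci.
subset_band_counts <- function(panel, idx) {
  ws <- band_workspace(panel, idx)
  colSums(ws$X)
}

# Mean per-locus Shannon information index from a band count vector,
# normalized by `norm_log` (log of the panel's total band count).
shannon_from_counts <- function(counts, locus_cols, norm_log) {
  tot_I <- 0
  for (cols in locus_cols) {
    cnt <- counts[cols]
    tot <- sum(cnt)
    if (tot == 0) next
    p <- cnt[cnt > 0] / tot
    tot_I <- tot_I - sum(p * log(p))
  }
  tot_I / length(locus_cols) / norm_log
}

locus_column_index <- function(panel) {
  lapply(names(panel$loci), function(ln) which(panel$band_locus == ln))
}

#' Mini-core subset objective
#'
#' @param panel a [germplasm_panel]
#' @param subset a [selection], ids or indices (size at least 2)
#' @param cfg a [minicore_config()]
#' @return the scalar objective value
#' @export
minicore_objective <- function(panel, subset, cfg = minicore_config()) {
  idx <- resolve_subset(panel, subset)
  if (length(idx) < 2) stop("subset must have at least 2 accessions")
  mr <- modified_rogers_distance(panel, idx)
  norm_log <- log(ncol(panel$bands))
  sh <- shannon_from_counts(subset_band_counts(panel, idx),
                            locus_column_index(panel), norm_log)
  cfg$weight_mr * mean(mr) + cfg$weight_shannon * sh
}

#' Extract a mini core by stochastic subset optimization
#'
#' Runs `n_replicas` independent stochastic local searches over subsets of
#' exactly `round(target_fraction * n)` accessions. Each search starts from
#' a random subset; a step swaps one selected accession against one
#' unselected accession drawn uniformly and accepts the move iff the
#' objective does not decrease; every `restart_every` steps a replica is
#' reseeded from the best subset found so far across replicas. The best
#' subset overall is returned.
#'
#' This is a deliberately simple greedy-with-restarts reimplementation of
#' mixed-replica subset search, not a port of any particular optimizer; on
#' small panels it provably reaches the exhaustive optimum (see the test
#' suite).
#'
#' @param panel a [germplasm_panel] with band data
#' @param cfg a [minicore_config()]
#' @return list with elements `selection` (a [selection], objective value
#'   in `$objective`) and `trace` (data.frame: step, replica, objective,
#'   accepted, best-so-far)
#' @export
build_minicore <- function(panel, cfg = minicore_config()) {
  n <- n_accessions(panel)
  k <- max(2L, round_half_up(cfg$target_fraction * n))
  if (k >= n) stop("target size must be smaller than the panel")
  mr <- as.matrix(modified_rogers_distance(panel))
  ws <- band_workspace(panel, seq_len(n))
  norm_log <- log(ncol(panel$bands))
  lcols <- locus_column_index(panel)
  npairs <- k * (k - 1) / 2

  obj_of <- function(state) {
    cfg$weight_mr * state$mr_sum / npairs +
      cfg$weight_shannon * shannon_from_counts(state$counts, lcols, norm_log)
  }
  make_state <- function(sel) {
    sub <- mr[sel, sel, drop = FALSE]
    list(sel = sel, mr_sum = sum(sub[upper.tri(sub)]),
         counts = colSums(ws$X[sel, , drop = FALSE]))
  }

  if (cfg$steps == 0L) {
    warning("step budget is 0; returning best random initial subset")
  }
  with_seed(cfg$seed, {
    best <- NULL
    best_obj <- -Inf
    trace <- vector("list", cfg$n_replicas)
    for (rep_i in seq_len(cfg$n_replicas)) {
      state <- make_state(sort(sample.int(n, k)))
      cur_obj <- obj_of(state)
      if (cur_obj > best_obj) {
        best_obj <- cur_obj
        best <- state
      }
      steps <- cfg$steps
      tr_obj <- numeric(steps)
      tr_acc <- logical(steps)
      tr_best <- numeric(steps)
      for (s in seq_len(steps)) {
        out_pos <- sample.int(k, 1L)
        out_acc <- state$sel[out_pos]
        in_acc <- sample(setdiff(seq_len(n), state$sel), 1L)
        others <- state$sel[-out_pos]
        d_mr <- sum(mr[in_acc, others]) - sum(mr[out_acc, others])
        new_counts <- state$counts - ws$X[out_acc, ] + ws$X[in_acc, ]
        new_obj <- cfg$weight_mr * (state$mr_sum + d_mr) / npairs +
          cfg$weight_shannon * shannon_from_counts(new_counts, lcols,
                                                   norm_log)
        accept <- new_obj >= cur_obj
        if (accept) {
          state$sel[out_pos] <- in_acc
          state$mr_sum <- state$mr_sum + d_mr
          state$counts <- new_counts
          cur_obj <- new_obj
          if (cur_obj > best_obj) {
            best_obj <- cur_obj
            best <- state
          }
        }
        tr_obj[s] <- cur_obj
        tr_acc[s] <- accept
        tr_best[s] <- best_obj
        if (cfg$restart_every > 0 && s %% cfg$restart_every == 0L) {
          state <- best
          cur_obj <- best_obj
        }
      }
      trace[[rep_i]] <- data.frame(replica = rep(rep_i, steps),
                                   step = seq_len(steps),
                                   objective = tr_obj, accepted = tr_acc,
                                   best = tr_best)
    }
    sel <- selection(panel, sort(best$sel), method = "minicore_optimizer",
                     seed = cfg$seed, fraction = cfg$target_fraction,
                     objective = best_obj)
    list(selection = sel, trace = do.call(rbind, trace))
  })
}

#' Mini core by random sampling within marker-diversity clusters
#'
#' Baseline strategy: cut the marker UPGMA dendrogram of the panel into
#' flat clusters and draw `fraction` of the accessions from each cluster
#' (minimum one), exactly as the core construction samples phenotypic
#' clusters.
#'
#' @param panel a [germplasm_panel]
#' @param tree a marker dendrogram of the panel (default: UPGMA of the
#'   Modified Rogers' distances)
#' @param fraction sampling fraction in (0, 1]
#' @param seed integer seed
#' @param cut_height,k cluster definition passed to [cut_tree()]
#'   (default `k = 10`)
#' @return a [selection]
#' @export
minicore_by_cluster_sampling <- function(panel, tree = NULL, fraction = 0.2,
                                         seed = 1L, cut_height = NULL,
                                         k = 10L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(tree)) tree <- upgma(modified_rogers_distance(panel))
  if (!setequal(tree$labels, panel$ids)) {
    stop("tree leaves must match panel accessions")
  }
  cl <- if (!is.null(cut_height)) {
    cut_tree(tree, height = cut_height)
  } else {
    cut_tree(tree, k = k)
  }
  idx_of <- match(tree$labels, panel$ids)
  clusters <- split(idx_of, cl)
  if (fraction == 1) {
    return(selection(panel, seq_len(n_accessions(panel)),
                     method = "cluster_sampling", seed = as.integer(seed),
                     fraction = 1))
  }
  with_seed(seed, {
    sw <- sample_within_clusters(clusters, fraction)
    selection(panel, sw$indices, method = "cluster_sampling",
              seed = as.integer(seed), fraction = fraction,
              strata_counts = data.frame(cluster = seq_along(clusters),
                                         size = lengths(clusters),
                                         selected = sw$counts))
  })
}

#' Mini core by geographic stratification only
#'
#' Baseline strategy: draw `fraction` of the accessions from each region
#' (minimum one per region), with no phenotypic or marker clustering.
#'
#' @inheritParams minicore_by_cluster_sampling
#' @return a [selection]
#' @export
minicore_by_region <- function(panel, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  regions <- panel$passport$region
  clusters <- split(seq_len(n_accessions(panel)), regions)
  with_seed(seed, {
    sw <- sample_within_clusters(clusters, fraction)
    selection(panel, sw$indices, method = "region_stratified",
              seed = as.integer(seed), fraction = fraction,
              strata_counts = data.frame(region = names(clusters),
                                         size = lengths(clusters),
                                         selected = sw$counts))
  })
}

#' Compare allele and genotype retention across mini cores
#'
#' Per locus and per selection: observed allele count and distinct band
#' pattern (genotype) count, in the layout of published strategy-comparison
#' tables. Per-selection column means and all pairwise mean differences
#' are attached as attributes.
#'
#' @param panel a [germplasm_panel]
#' @param selections named list of at least two [selection]s (or index
#'   vectors)
#' @return data.frame of class `minicore_comparison` with one row per
#'   locus; attributes `means` and `mean_differences`
#' @export
compare_minicores <- function(panel, selections) {
  if (length(selections) < 2) stop("need at least 2 selections")
  if (is.null(names(selections))) {
    names(selections) <- paste0("set", seq_along(selections))
  }
  reps <- lapply(selections, function(s) count_alleles_genotypes(panel, s))
  out <- data.frame(locus = reps[[1]]$locus, stringsAsFactors = FALSE)
  for (nm in names(reps)) {
    out[[paste0("alleles_", nm)]] <- reps[[nm]]$n_alleles
    out[[paste0("genotypes_", nm)]] <- reps[[nm]]$n_genotypes
  }
  means <- colMeans(out[, -1, drop = FALSE])
  nms <- names(reps)
  pair <- utils::combn(nms, 2)
  md <- data.frame(
    a = pair[1, ], b = pair[2, ],
    d_alleles = means[paste0("alleles_", pair[1, ])] -
      means[paste0("alleles_", pair[2, ])],
    d_genotypes = means[paste0("genotypes_", pair[1, ])] -
      means[paste0("genotypes_", pair[2, ])],
    row.names = NULL)
  attr(out, "means") <- means
  attr(out, "mean_differences") <- md
  class(out) <- c("minicore_comparison", "data.frame")
  out
}
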