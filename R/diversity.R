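#' Per-locus band (allele) relative frequencies
#'
#' For each locus, the frequency of a band is the number of accessions in
#' the (sub)set carrying it divided by the total number of band
#' observations at that locus. Accessions unscored at a locus are excluded
#' from that locus only; a locus with no scored accession is flagged empty
#' rather than producing `NaN`s.
#'
#' @param panel a [germplasm_panel]
#' @param subset optional [selection], ids or indices; default whole panel
#' @return an `allele_freq_table`: named list per locus with `freq` (named
#'   frequency vector), `counts` (band counts) and `n_scored`
#' @export
allele_frequencies <- function(panel, subset = NULL) {
  idx <- resolve_subset(panel, subset)
  bands <- panel$bands[idx, , drop = FALSE]
  out <- lapply(names(panel$loci), function(ln) {
    cols <- which(panel$band_locus == ln)
    sub <- bands[, cols, drop = FALSE]
    scored <- rowSums(is.na(sub)) == 0L
    counts <- colSums(sub[scored, , drop = FALSE])
    names(counts) <- panel$loci[[ln]]
    tot <- sum(counts)
    list(freq = if (tot > 0) counts / tot else counts * NA_real_,
         counts = counts, n_scored = sum(scored), empty = tot == 0)
  })
  names(out) <- names(panel$loci)
  structure(out, class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d loci (%d empty)\n", length(x),
              sum(vapply(x, `[[`, TRUE, "empty"))))
  invisible(x)
}

check_freqs <- function(p) {
  if (any(p < 0)) stop("frequencies must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  p
}

# Apply a per-frequency-vector statistic to a numeric vector or a whole
# allele_freq_table (NA for empty loci).
per_locus <- function(freqs, f) {
  if (inherits(freqs, "allele_freq_table")) {
    vapply(freqs, function(l) {
      if (isTRUE(l$empty)) NA_real_ else f(check_freqs(l$freq))
    }, 0)
  } else {
    f(check_freqs(freqs))
  }
}

#' Shannon information index
#'
#' `I = -sum(p_i * log(p_i))` over the band frequencies of a locus, with
#' zero-frequency terms contributing 0. Natural logarithms.
#'
#' @param freqs a frequency vector or an [allele_frequencies()] table
#' @return numeric (one value per locus for a table)
#' @export
shannon_information_index <- function(freqs) {
  per_locus(freqs, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Nei's expected heterozygosity (gene diversity)
#'
#' `H = 1 - sum(p_i^2)`: the probability that two alleles drawn at random
#' from the population differ.
#'
#' @inheritParams shannon_information_index
#' @return numeric (one value per locus for a table)
#' @export
nei_expected_heterozygosity <- function(freqs) {
  per_locus(freqs, function(p) 1 - sum(p^2))
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @inheritParams shannon_information_index
#' @return numeric (one value per locus for a table)
#' @export
pic <- function(freqs) {
  per_locus(freqs, function(p) {
    s2 <- sum(p^2)
    s4 <- sum(p^4)
    1 - s2 - (s2^2 - s4)
  })
}

#' Per-locus allele and genotype counts with diversity indices
#'
#' For each locus: the number of bands observed at nonzero frequency, the
#' number of distinct band patterns (genotypes) among scored accessions,
#' the Shannon information index, Nei's expected heterozygosity and PIC.
#' Totals (sum of allele counts; number of distinct multilocus genotypes
#' among fully scored accessions) are attached as attributes.
#'
#' @param panel a [germplasm_panel]
#' @param subset optional [selection], ids or indices
#' @return a data.frame of class `diversity_report` with one row per locus
#'   and attributes `total_alleles`, `total_multilocus_genotypes`,
#'   `n_accessions`
#' @export
count_alleles_genotypes <- function(panel, subset = NULL) {
  idx <- resolve_subset(panel, subset)
  ft <- allele_frequencies(panel, idx)
  bands <- panel$bands[idx, , drop = FALSE]
  rows <- lapply(names(panel$loci), function(ln) {
    cols <- which(panel$band_locus == ln)
    sub <- bands[, cols, drop = FALSE]
    scored <- rowSums(is.na(sub)) == 0L
    pat <- apply(sub[scored, , drop = FALSE], 1, paste, collapse = "")
    l <- ft[[ln]]
    data.frame(locus = ln,
               n_alleles = sum(l$counts > 0),
               n_genotypes = length(unique(pat)),
               shannon = if (l$empty) NA_real_ else
                 shannon_information_index(l$freq),
               nei = if (l$empty) NA_real_ else
                 nei_expected_heterozygosity(l$freq),
               pic = if (l$empty) NA_real_ else pic(l$freq),
               n_scored = l$n_scored,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  full <- rowSums(is.na(bands)) == 0L
  mlg <- apply(bands[full, , drop = FALSE], 1, paste, collapse = "")
  attr(rep, "total_alleles") <- sum(rep$n_alleles)
  attr(rep, "total_multilocus_genotypes") <- length(unique(mlg))
  attr(rep, "n_accessions") <- length(idx)
  class(rep) <- c("diversity_report", "data.frame")
  rep
}

#' Column means, SDs and totals of a per-locus (or per-descriptor) report
#'
#' Reproduces the summary arithmetic of published per-locus marker tables:
#' for every numeric column, the column mean, standard deviation and sum.
#'
#' @param report data.frame with one row per locus/descriptor
#' @return data.frame with rows `mean`, `sd`, `total` and one column per
#'   numeric input column
#' @export
summarize_report_columns <- function(report) {
  num <- vapply(report, is.numeric, TRUE)
  x <- as.data.frame(report)[, num, drop = FALSE]
  out <- rbind(mean = colMeans(x, na.rm = TRUE),
               sd = apply(x, 2, stats::sd, na.rm = TRUE),
               total = colSums(x, na.rm = TRUE))
  as.data.frame(out)
}

#' Equal-width class boundaries for a descriptor
#'
#' Bin edges spanning the descriptor's range in the reference panel,
#' divided into `n_classes` equal-width classes. Subsets binned on the
#' reference edges share one class system with the whole collection.
#'
#' @param panel the reference [germplasm_panel]
#' @param descriptor descriptor code
#' @param n_classes number of classes; default: the descriptor's declared
#'   `n_classes`
#' @return numeric vector of `n_classes + 1` edges
#' @export
trait_bin_edges <- function(panel, descriptor, n_classes = NULL) {
  x <- panel$traits[, descriptor]
  x <- x[!is.na(x)]
  if (!length(x)) stop("all values missing for ", descriptor)
  if (is.null(n_classes)) {
    n_classes <- panel$descriptors$n_classes[
      match(descriptor, panel$descriptors$code)]
  }
  if (n_classes < 2) stop("n_classes must be >= 2")
  seq(min(x), max(x), length.out = n_classes + 1)
}

bin_proportions <- function(x, edges) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing values to bin")
  # clamp so values at/beyond the reference range land in the outer classes
  x <- pmin(pmax(x, edges[1]), edges[length(edges)])
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                               all.inside = TRUE),
                  nbins = length(edges) - 1)
  cnt / sum(cnt)
}

#' Shannon-Weaver diversity index of a quantitative trait
#'
#' Values are binned into `n_classes` equal-width classes over the
#' reference panel's range; the index is the Shannon entropy of the class
#' proportions normalized by `log(n_classes)`, so it lies in `[0, 1]`.
#'
#' @param panel a [germplasm_panel]
#' @param descriptor descriptor code
#' @param n_classes number of classes (default: declared `n_classes`)
#' @param bin_edges optional explicit edges (e.g. from the whole collection
#'   via [trait_bin_edges()]); default: computed from `panel`
#' @param subset optional [selection], ids or indices
#' @return normalized diversity index in `[0, 1]`
#' @export
trait_shannon_index <- function(panel, descriptor, n_classes = NULL,
                                bin_edges = NULL, subset = NULL) {
  if (is.null(n_classes)) {
    n_classes <- panel$descriptors$n_classes[
      match(descriptor, panel$descriptors$code)]
  }
  if (is.na(n_classes) || n_classes < 2) stop("n_classes must be >= 2")
  if (is.null(bin_edges)) {
    bin_edges <- trait_bin_edges(panel, descriptor, n_classes)
  }
  if (diff(range(bin_edges)) == 0) {
    warning("zero-width class range for ", descriptor)
    return(0)
  }
  idx <- resolve_subset(panel, subset)
  x <- panel$traits[idx, descriptor]
  if (all(is.na(x))) stop("all values missing for ", descriptor)
  p <- bin_proportions(x, bin_edges)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n_classes)
}

#' Trait summary statistics for a panel or subset
#'
#' Per descriptor: count, mean and sample variance (`n - 1` denominator)
#' over non-missing values, plus the normalized Shannon-Weaver index binned
#' on the reference panel's class system. Pairwise Pearson trait
#' correlations are attached as an attribute.
#'
#' @param panel a [germplasm_panel] (also the binning reference)
#' @param subset optional [selection], ids or indices
#' @return data.frame of class `trait_report` (one row per descriptor) with
#'   attribute `correlations`
#' @export
summary_stats <- function(panel, subset = NULL) {
  idx <- resolve_subset(panel, subset)
  codes <- panel$descriptors$code
  rows <- lapply(codes, function(cd) {
    x <- panel$traits[idx, cd]
    x <- x[!is.na(x)]
    nc <- panel$descriptors$n_classes[match(cd, panel$descriptors$code)]
    data.frame(descriptor = cd, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               variance = if (length(x) >= 2) stats::var(x) else NA_real_,
               variance_defined = length(x) >= 2,
               n_classes = nc,
               shannon = trait_shannon_index(panel, cd, subset = idx),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  cors <- stats::cor(panel$traits[idx, codes, drop = FALSE],
                     use = "pairwise.complete.obs")
  attr(rep, "correlations") <- cors
  class(rep) <- c("trait_report", "data.frame")
  rep
}
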