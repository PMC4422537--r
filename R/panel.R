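#' Construct a germplasm panel
#'
#' A `germplasm_panel` is the container consumed by every stage of the
#' core/mini-core pipeline: passport data (accession id, country, region
#' stratum), quantitative trait scores for a set of descriptors, and a
#' dominant-scored SSR band matrix (one 0/1 column per band, bands grouped
#' by locus).
#'
#' Missingness is kept explicit throughout: a missing trait value is `NA`
#' and is excluded pairwise from distances and summaries; a missing band
#' cell means the accession could not be scored at that locus (it is *not*
#' treated as band absence) and the accession is dropped from that locus
#' in frequency counts.
#'
#' @param passport data.frame with columns `id`, `country`, `region`; one
#'   row per accession, ids unique and nonempty. Row order defines the
#'   panel order.
#' @param traits numeric matrix or data.frame, one row per accession
#'   (rownames or row order matching `passport$id`), one column per
#'   descriptor code. `NA` marks missing.
#' @param bands integer matrix or data.frame of 0/1/`NA`, one row per
#'   accession, one column per band named `"locus:band"`.
#' @param descriptors data.frame with columns `code`, `label`, `units`,
#'   `n_classes` (number of phenotypic classes used for binning,
#'   at least 2). Defaults to a minimal frame built from `colnames(traits)`
#'   with 10 classes each.
#' @param loci named list mapping locus name to the character vector of its
#'   band labels. Defaults to the grouping implied by the `"locus:band"`
#'   column names of `bands`.
#'
#' @return An object of class `germplasm_panel` with elements `ids`,
#'   `passport`, `traits`, `bands`, `descriptors`, `loci`, `band_locus`.
#' @export
germplasm_panel <- function(passport, traits, bands, descriptors = NULL,
                            loci = NULL) {
  passport <- as.data.frame(passport, stringsAsFactors = FALSE)
  need <- c("id", "country", "region")
  if (!all(need %in% names(passport))) {
    stop("passport must have columns ", paste(need, collapse = ", "))
  }
  ids <- as.character(passport$id)
  if (any(!nzchar(ids)) || anyNA(ids)) stop("accession ids must be nonempty")
  if (anyDuplicated(ids)) {
    stop("duplicate accession ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  traits <- as.matrix(as.data.frame(traits))
  storage.mode(traits) <- "double"
  if (nrow(traits) != length(ids)) stop("traits row count != passport rows")
  rownames(traits) <- ids
  if (is.null(colnames(traits))) stop("traits must have descriptor colnames")

  bands <- as.matrix(as.data.frame(bands))
  storage.mode(bands) <- "integer"
  if (nrow(bands) != length(ids)) stop("bands row count != passport rows")
  rownames(bands) <- ids
  if (is.null(colnames(bands))) stop("band columns must be named locus:band")
  bad <- which(!(bands %in% c(0L, 1L, NA_integer_)), arr.ind = FALSE)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(bands))
    stop(sprintf("non-binary band value %s at row %s (id %s), column %s",
                 bands[bad[1]], rc[1], ids[rc[1]], colnames(bands)[rc[2]]))
  }

  if (is.null(loci)) {
    parts <- strsplit(colnames(bands), ":", fixed = TRUE)
    if (any(lengths(parts) < 2)) {
      stop("band column names must be of the form locus:band")
    }
    locus_of <- vapply(parts, `[[`, "", 1L)
    band_of <- vapply(parts, function(p) paste(p[-1], collapse = ":"), "")
    loci <- split(band_of, factor(locus_of, levels = unique(locus_of)))
  }
  band_locus <- rep(names(loci), lengths(loci))
  expect_cols <- paste(band_locus, unlist(loci, use.names = FALSE), sep = ":")
  if (!setequal(expect_cols, colnames(bands)) ||
      length(expect_cols) != ncol(bands)) {
    stop("band columns do not match declared loci/band labels")
  }
  bands <- bands[, expect_cols, drop = FALSE]
  for (ln in names(loci)) {
    if (anyDuplicated(loci[[ln]])) stop("duplicate band labels in locus ", ln)
    if (!length(loci[[ln]])) stop("locus ", ln, " declares no bands")
  }

  if (is.null(descriptors)) {
    descriptors <- data.frame(code = colnames(traits),
                              label = colnames(traits),
                              units = "", n_classes = 10L,
                              stringsAsFactors = FALSE)
  }
  descriptors <- as.data.frame(descriptors, stringsAsFactors = FALSE)
  if (anyDuplicated(descriptors$code)) stop("duplicate descriptor codes")
  if (any(descriptors$n_classes < 2)) stop("descriptor n_classes must be >= 2")
  if (!setequal(descriptors$code, colnames(traits))) {
    stop("descriptor codes do not match trait columns")
  }
  traits <- traits[, descriptors$code, drop = FALSE]

  structure(list(ids = ids, passport = passport, traits = traits,
                 bands = bands, descriptors = descriptors, loci = loci,
                 band_locus = band_locus),
            class = "germplasm_panel")
}

#' @export
print.germplasm_panel <- function(x, ...) {
  cat(sprintf(paste0("germplasm_panel: %d accessions, %d regions, ",
                     "%d descriptors, %d loci (%d bands)\n"),
              length(x$ids), length(unique(x$passport$region)),
              nrow(x$descriptors), length(x$loci), ncol(x$bands)))
  invisible(x)
}

#' Number of accessions in a panel
#' @param panel a `germplasm_panel`
#' @return integer count
#' @export
n_accessions <- function(panel) length(panel$ids)

#' Restrict a panel to a subset of accessions
#'
#' @param panel a `germplasm_panel`
#' @param subset integer indices, accession ids, or a [selection]
#' @return a `germplasm_panel` containing the selected accessions, in
#'   selection order
#' @export
subset_panel <- function(panel, subset) {
  idx <- resolve_subset(panel, subset)
  germplasm_panel(panel$passport[idx, , drop = FALSE],
                  panel$traits[idx, , drop = FALSE],
                  panel$bands[idx, , drop = FALSE],
                  panel$descriptors, panel$loci)
}

# Normalize a subset argument (NULL, selection, ids, logical or integer
# indices) to validated integer panel indices.
resolve_subset <- function(panel, subset) {
  if (is.null(subset)) return(seq_along(panel$ids))
  if (inherits(subset, "germ_selection")) subset <- subset$indices
  if (is.character(subset)) {
    idx <- match(subset, panel$ids)
    if (anyNA(idx)) {
      stop("unknown accession ids: ",
           paste(subset[is.na(idx)], collapse = ", "))
    }
    return(idx)
  }
  if (is.logical(subset)) subset <- which(subset)
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop("subset indices must be unique")
  if (any(subset < 1L | subset > length(panel$ids))) {
    stop("subset indices out of bounds")
  }
  subset
}

# n x L logical matrix: TRUE where an accession is unscored at a locus
# (any NA among the locus's band columns).
locus_missing <- function(panel) {
  L <- names(panel$loci)
  out <- matrix(FALSE, nrow(panel$bands), length(L),
                dimnames = list(panel$ids, L))
  for (j in seq_along(L)) {
    cols <- which(panel$band_locus == L[j])
    out[, j] <- rowSums(is.na(panel$bands[, cols, drop = FALSE])) > 0L
  }
  out
}

#' Create a selection (an ordered subset of panel accessions)
#'
#' A `germ_selection` records which accessions were selected plus the
#' provenance needed to reproduce the draw: the method, the seed, the
#' sampling fraction, per-stratum counts and (for optimizer selections)
#' the objective value attained.
#'
#' @param panel the `germplasm_panel` the indices refer to
#' @param indices integer panel indices, unique and in-bounds
#' @param method short method name (e.g. `"stratified_cluster"`)
#' @param seed integer seed used for the draw, or `NA`
#' @param fraction nominal sampling fraction, or `NA`
#' @param strata_counts optional data.frame of per-stratum selected counts
#' @param objective optional objective value (mini-core optimizer)
#' @return object of class `germ_selection`
#' @export
selection <- function(panel, indices, method = "manual", seed = NA_integer_,
                      fraction = NA_real_, strata_counts = NULL,
                      objective = NA_real_) {
  indices <- resolve_subset(panel, indices)
  structure(list(indices = indices, ids = panel$ids[indices],
                 method = method, seed = seed, fraction = fraction,
                 strata_counts = strata_counts, objective = objective),
            class = "germ_selection")
}

#' @export
print.germ_selection <- function(x, ...) {
  cat(sprintf("germ_selection: %d accessions (method %s, seed %s%s)\n",
              length(x$indices), x$method, x$seed,
              if (is.finite(x$objective)) {
                sprintf(", objective %.4f", x$objective)
              } else ""))
  invisible(x)
}

#' @export
length.germ_selection <- function(x) length(x$indices)
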