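#' Read a germplasm panel from its CSV trio
#'
#' Reads the passport, trait and band tables and joins them by accession id
#' into a validated [germplasm_panel]. The file dialect is fixed: UTF-8 CSV,
#' comma separator, `.` decimal point, empty cell = missing. Panel order is
#' the row order of the passport file, regardless of the order of the other
#' two files.
#'
#' @param trait_path CSV with column `id` plus one numeric column per
#'   descriptor code.
#' @param band_path CSV with column `id` plus one 0/1 column per band,
#'   named `"locus:band"`.
#' @param passport_path CSV with columns `id`, `country`, `region`.
#' @param schema optional list (or path to a YAML file) with elements
#'   `descriptors` (data.frame with `code`, `label`, `units`, `n_classes`)
#'   and/or `loci` (named list locus -> band labels). Omitted pieces are
#'   inferred from the files.
#' @return a [germplasm_panel]
#' @export
read_panel <- function(trait_path, band_path, passport_path, schema = NULL) {
  for (p in c(trait_path, band_path, passport_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  if (is.character(schema)) schema <- yaml::read_yaml(schema)

  passport <- utils::read.csv(passport_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  traits <- utils::read.csv(trait_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  bands <- utils::read.csv(band_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (nm in c("passport", "traits", "bands")) {
    df <- get(nm)
    if (!"id" %in% names(df)) stop(nm, " file has no 'id' column")
    ids <- as.character(df$id)
    if (anyDuplicated(ids)) {
      stop("duplicate accession ids in ", nm, " file: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }

  ids <- as.character(passport$id)
  for (nm in c("traits", "bands")) {
    other <- as.character(get(nm)$id)
    extra <- setdiff(other, ids)
    miss <- setdiff(ids, other)
    if (length(extra) || length(miss)) {
      stop("id mismatch between passport and ", nm, " files; ",
           if (length(miss)) paste0("missing from ", nm, ": ",
                                    paste(miss, collapse = ", "), "; ") else "",
           if (length(extra)) paste0("unknown in ", nm, ": ",
                                     paste(extra, collapse = ", ")) else "")
    }
  }

  tmat <- as.matrix(traits[match(ids, traits$id), setdiff(names(traits), "id"),
                           drop = FALSE])
  bmat <- as.matrix(bands[match(ids, bands$id), setdiff(names(bands), "id"),
                          drop = FALSE])
  germplasm_panel(passport, tmat, bmat,
                  descriptors = schema$descriptors, loci = schema$loci)
}

#' Write a panel back to its CSV trio
#'
#' Inverse of [read_panel()]; writing and re-reading is an identity on the
#' panel, and a second write is byte-identical.
#'
#' @param panel a [germplasm_panel]
#' @param trait_path,band_path,passport_path output CSV paths
#' @return invisibly, the three paths
#' @export
write_panel <- function(panel, trait_path, band_path, passport_path) {
  utils::write.csv(panel$passport[, c("id", "country", "region")],
                   passport_path, row.names = FALSE, quote = FALSE, na = "")
  td <- data.frame(id = panel$ids, panel$traits, check.names = FALSE)
  utils::write.csv(td, trait_path, row.names = FALSE, quote = FALSE, na = "")
  bd <- data.frame(id = panel$ids, panel$bands, check.names = FALSE)
  utils::write.csv(bd, band_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(trait_path, band_path, passport_path))
}

#' Export a dendrogram as Newick
#'
#' Writes a UPGMA merge tree so that the branch length from a leaf to an
#' internal node equals that node's merge height (branch lengths are
#' differences of merge heights). A two-leaf tree merged at height 0.5 is
#' written as `(A:0.5,B:0.5);`.
#'
#' @param tree an `hclust`-like merge tree (e.g. from [upgma()])
#' @param path output file
#' @return invisibly, `path`
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "hclust")) stop("tree must be an hclust-like object")
  # ape halves hclust heights on conversion; double so leaf->node = height
  t2 <- tree
  t2$height <- 2 * t2$height
  phy <- ape::as.phylo(t2)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a Newick dendrogram back into merge-tree form
#'
#' Reads an ultrametric Newick tree written by [write_newick()] and returns
#' the corresponding `hclust` object (merge heights equal leaf-to-node path
#' lengths).
#'
#' @param path Newick file
#' @return an object of class `hclust`
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  h <- ape::as.hclust.phylo(phy)
  h$height <- h$height / 2
  h$method <- "upgma"
  h
}

#' Write a selection to CSV with provenance header
#'
#' Emits comment lines (`# method: ...`, `# seed: ...`, `# fraction: ...`,
#' `# objective: ...`) followed by a one-column CSV of accession ids in
#' selection order.
#'
#' @param sel a [selection]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_selection <- function(sel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", sel$method),
               sprintf("# seed: %s", sel$seed),
               sprintf("# fraction: %s", sel$fraction),
               sprintf("# objective: %s", sel$objective),
               "id"), con)
  if (length(sel$ids)) writeLines(sel$ids, con)
  invisible(path)
}

#' Read a selection CSV written by [write_selection()]
#'
#' @param path selection CSV
#' @param panel the panel the ids refer to
#' @return a [selection]
#' @export
read_selection <- function(path, panel) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  meta <- list()
  for (l in hdr) {
    kv <- sub("^# ([a-z]+): (.*)$", "\\1\x01\\2", l)
    kv <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!startsWith(lines, "#")]
  ids <- body[-1]  # drop "id" header
  num <- function(x) if (is.null(x) || x == "NA") NA_real_ else as.numeric(x)
  selection(panel, ids, method = meta$method %||% "unknown",
            seed = as.integer(num(meta$seed)), fraction = num(meta$fraction),
            objective = num(meta$objective))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published mungbean collection reference summaries
#'
#' Loads the transcribed per-descriptor and per-locus summary tables
#' reported for the AVRDC mungbean whole, core and mini core collections:
#' trait means/variances/test p-values/Shannon indices, per-locus allele and
#' genotype counts with Shannon and Nei indices, and the per-locus allele
#' and genotype counts of the three competing mini-core strategies.
#'
#' @return list with data.frames `trait_summary`, `marker_diversity`,
#'   `minicore_strategies`
#' @export
mungbean_reference_tables <- function() {
  pth <- function(f) system.file("extdata", f, package = "germcore",
                                 mustWork = TRUE)
  list(
    trait_summary = utils::read.csv(pth("mungbean_trait_summary.csv"),
                                    check.names = FALSE),
    marker_diversity = utils::read.csv(pth("mungbean_ssr_core_minicore.csv"),
                                       check.names = FALSE),
    minicore_strategies =
      utils::read.csv(pth("mungbean_ssr_minicore_strategies.csv"),
                      check.names = FALSE)
  )
}
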