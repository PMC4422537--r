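# Fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdirs.

# A fully deterministic 6-accession panel: 2 regions, 2 traits, 2 loci
# with 2 bands each, one band per locus per accession.
make_toy_panel <- function() {
  passport <- data.frame(
    id = paste0("A", 1:6),
    country = c("India", "India", "Thailand", "Thailand", "China", "China"),
    region = c("South Asia", "South Asia", "Southeast Asia",
               "Southeast Asia", "East Asia", "East Asia"),
    stringsAsFactors = FALSE)
  traits <- cbind(T1 = c(1, 2, 3, 4, 5, 6),
                  T2 = c(10, 10, 20, 20, 30, 30))
  bands <- cbind(
    "L1:a" = c(1L, 1L, 0L, 0L, 1L, 0L),
    "L1:b" = c(0L, 0L, 1L, 1L, 0L, 1L),
    "L2:a" = c(1L, 0L, 1L, 0L, 1L, 0L),
    "L2:b" = c(0L, 1L, 0L, 1L, 0L, 1L))
  germplasm_panel(passport, traits, bands)
}

# Panel whose band profiles are given explicitly: `profiles` is a list of
# per-accession band picks, one band label index per locus.
make_band_panel <- function(profiles, n_bands_per_locus) {
  n <- length(profiles)
  L <- length(n_bands_per_locus)
  cols <- unlist(lapply(seq_len(L), function(l) {
    paste0("L", l, ":b", seq_len(n_bands_per_locus[l]))
  }))
  bands <- matrix(0L, n, length(cols),
                  dimnames = list(NULL, cols))
  offs <- c(0L, cumsum(n_bands_per_locus))
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      pick <- profiles[[i]][l]
      cols <- (offs[l] + 1):(offs[l] + n_bands_per_locus[l])
      if (is.na(pick)) {
        bands[i, cols] <- NA_integer_  # locus unscored for this accession
      } else {
        bands[i, offs[l] + pick] <- 1L
      }
    }
  }
  passport <- data.frame(id = sprintf("S%02d", seq_len(n)),
                         country = "x", region = "R1",
                         stringsAsFactors = FALSE)
  traits <- cbind(T1 = seq_len(n))
  germplasm_panel(passport, traits, bands)
}

# Write a panel's CSV trio into a fresh tempdir; returns the three paths.
write_panel_fixture <- function(panel, dir = withr::local_tempdir(
                                  .local_envir = parent.frame())) {
  paths <- file.path(dir, c("traits.csv", "bands.csv", "passport.csv"))
  write_panel(panel, paths[1], paths[2], paths[3])
  names(paths) <- c("traits", "bands", "passport")
  paths
}

random_freqs <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# Independent brute-force UPGMA: average inter-cluster distances are
# recomputed from the ORIGINAL matrix at every step (no Lance-Williams
# update), with the same lexicographic smallest-label tie rule. Returns
# the cophenetic matrix, which identifies the tree up to representation.
brute_upgma_cophenetic <- function(m) {
  m <- as.matrix(m)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        avg <- mean(m[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(labels[clusters[[i]]]),
                      min(labels[clusters[[j]]])))
        if (is.null(best) || avg < best$avg - 1e-12 ||
            (abs(avg - best$avg) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, avg = avg, key = key)
        }
      }
    }
    coph[clusters[[best$i]], clusters[[best$j]]] <- best$avg
    coph[clusters[[best$j]], clusters[[best$i]]] <- best$avg
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  coph
}

# Random symmetric distance matrix with zero diagonal; `integer_valued`
# forces heavy ties.
random_dist_matrix <- function(n, integer_valued = FALSE) {
  m <- matrix(0, n, n)
  v <- if (integer_valued) sample(1:4, n * (n - 1) / 2, replace = TRUE)
       else stats::runif(n * (n - 1) / 2, 0.5, 3)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}
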