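#' Default mungbean trait descriptors
#'
#' The eight quantitative descriptors used to characterize the mungbean
#' collection, with the number of phenotypic classes used for binning:
#' primary leaf length/width, plant height at flowering and at maturity,
#' days to 50% flowering, pod length, seeds per pod and 1000-seed weight.
#'
#' @return data.frame with columns `code`, `label`, `units`, `n_classes`
#' @export
mungbean_descriptors <- function() {
  data.frame(
    code = c("V040", "V050", "V120", "V130", "V400", "V510", "V700", "V770"),
    label = c("primary leaf length", "primary leaf width",
              "plant height at flowering", "plant height at maturity",
              "days to 50% flowering", "pod length", "seeds per pod",
              "1000 seed weight"),
    units = c("cm", "cm", "cm", "cm", "days", "cm", "count", "g"),
    n_classes = c(11L, 10L, 15L, 14L, 11L, 11L, 13L, 14L),
    stringsAsFactors = FALSE
  )
}

# Whole-collection trait means and variances of the mungbean panel the
# generator is calibrated to.
default_trait_params <- function() {
  data.frame(
    code = c("V040", "V050", "V120", "V130", "V400", "V510", "V700", "V770"),
    mean = c(4.5, 1.7, 22.2, 40.5, 44.2, 7.3, 11.0, 37.5),
    var = c(0.24, 0.05, 36.89, 149.75, 14.49, 1.01, 1.59, 87.24),
    stringsAsFactors = FALSE
  )
}

#' Default descriptor correlation matrix
#'
#' A realistic correlation structure for the eight mungbean descriptors:
#' leaf length and width, and the two plant heights, are strongly
#' correlated; later-flowering plants are taller at maturity; longer pods
#' carry more and heavier seeds, with a slight trade-off between seed
#' number and seed weight. Used as the generator's default within-
#' subpopulation trait correlation.
#'
#' @return positive-definite 8 x 8 correlation matrix with descriptor
#'   codes as dimnames
#' @export
mungbean_trait_correlations <- function() {
  codes <- c("V040", "V050", "V120", "V130", "V400", "V510", "V700", "V770")
  C <- diag(8)
  dimnames(C) <- list(codes, codes)
  set2 <- function(a, b, v) {
    C[a, b] <<- v
    C[b, a] <<- v
  }
  set2("V040", "V050", 0.75)
  set2("V120", "V130", 0.85)
  set2("V040", "V120", 0.3); set2("V040", "V130", 0.3)
  set2("V050", "V120", 0.3); set2("V050", "V130", 0.3)
  set2("V400", "V120", 0.4); set2("V400", "V130", 0.5)
  set2("V510", "V700", 0.6); set2("V510", "V770", 0.45)
  set2("V700", "V770", -0.15)
  set2("V770", "V040", 0.3); set2("V770", "V050", 0.3)
  C
}

# Rough origin shares of a large Asian-centred germplasm collection.
default_region_weights <- function() {
  c("South Asia" = 0.35, "Southeast Asia" = 0.25, "East Asia" = 0.20,
    "Southwest Asia" = 0.07, "Africa" = 0.05, "Americas" = 0.04,
    "Europe" = 0.02, "Oceania" = 0.02)
}

default_region_countries <- function() {
  list("South Asia" = c("India", "Pakistan", "Bangladesh", "Sri Lanka"),
       "Southeast Asia" = c("Philippines", "Thailand", "Indonesia", "Vietnam"),
       "East Asia" = c("China", "Korea", "Taiwan", "Japan"),
       "Southwest Asia" = c("Iran", "Afghanistan", "Turkey"),
       "Africa" = c("Kenya", "Ethiopia", "Nigeria"),
       "Americas" = c("USA", "Brazil", "Peru"),
       "Europe" = c("Russia", "Ukraine"),
       "Oceania" = c("Australia", "Papua New Guinea"))
}

#' Build a simulation configuration
#'
#' Parameters of the synthetic germplasm panel generator. Defaults emulate a
#' large multi-region mungbean collection: eight quantitative descriptors
#' with the collection's published means and variances, 20 SSR loci with 3
#' to 13 bands (alleles) each, and two subpopulations whose allele
#' frequencies are separated by a `divergence` mixing weight.
#'
#' @param n_accessions number of accessions to simulate
#' @param region_weights named probability vector over region strata
#'   (must sum to 1)
#' @param trait_params data.frame with columns `code`, `mean`, `var`
#'   (shared by all subpopulations) or a list of such data.frames, one per
#'   subpopulation
#' @param n_loci number of SSR loci
#' @param alleles_per_locus_range integer interval (within 2..30) from which
#'   each locus's band count is drawn uniformly
#' @param n_subpops number of subpopulations
#' @param divergence real in `[0, 1)`: Fst-like separation of subpopulation
#'   allele frequencies around the shared base (hierarchical Dirichlet with
#'   concentration `(1 - divergence) / divergence`); 0 means no structure
#' @param trait_divergence real in `[0, 1)`: separation of the
#'   subpopulations' phenotypes, expressed as the fraction of each trait's
#'   SD placed between subpopulation means (subpopulation means are
#'   `mean +/- trait_divergence * sd`, within-subpopulation SD is shrunk to
#'   `sd * sqrt(1 - trait_divergence^2)`, so the whole-panel mean and
#'   variance stay at their configured values). The default 0.6 produces
#'   the two overlapping phenotypic mega-clusters characteristic of large
#'   germplasm collections. Ignored when `trait_params` is given per
#'   subpopulation.
#' @param trait_cor within-subpopulation descriptor correlation matrix
#'   (default: [mungbean_trait_correlations()]); pass `diag(k)` for
#'   independent traits
#' @param seed integer seed; the whole simulation is reproducible from it
#' @return a validated list of class `sim_config`
#' @export
simulation_config <- function(n_accessions = 1000,
                              region_weights = default_region_weights(),
                              trait_params = default_trait_params(),
                              n_loci = 20,
                              alleles_per_locus_range = c(3L, 13L),
                              n_subpops = 2,
                              divergence = 0.3,
                              trait_divergence = 0.6,
                              trait_cor = NULL,
                              seed = 1L) {
  if (n_accessions < 1) stop("n_accessions must be positive")
  if (abs(sum(region_weights) - 1) > 1e-9) {
    stop("region_weights must sum to 1")
  }
  if (is.null(names(region_weights))) stop("region_weights must be named")
  if (any(region_weights < 0)) stop("region_weights must be nonnegative")
  tp <- if (is.data.frame(trait_params)) list(trait_params) else trait_params
  for (d in tp) {
    if (!all(c("code", "mean", "var") %in% names(d))) {
      stop("trait_params needs columns code, mean, var")
    }
    if (any(d$var <= 0)) stop("trait variances must be positive")
  }
  r <- as.integer(alleles_per_locus_range)
  if (length(r) != 2 || r[1] > r[2] || r[1] < 2 || r[2] > 30) {
    stop("alleles_per_locus_range must lie within [2, 30]")
  }
  if (n_subpops < 1) stop("n_subpops must be positive")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (trait_divergence < 0 || trait_divergence >= 1) {
    stop("trait_divergence must be in [0, 1)")
  }
  k <- nrow(tp[[1]])
  if (is.null(trait_cor)) {
    dflt <- mungbean_trait_correlations()
    trait_cor <- if (identical(tp[[1]]$code, colnames(dflt))) dflt else diag(k)
  }
  if (!is.matrix(trait_cor) || any(dim(trait_cor) != k)) {
    stop("trait_cor must be a ", k, "x", k, " matrix")
  }
  structure(list(n_accessions = as.integer(n_accessions),
                 region_weights = region_weights, trait_params = trait_params,
                 n_loci = as.integer(n_loci), alleles_per_locus_range = r,
                 n_subpops = as.integer(n_subpops), divergence = divergence,
                 trait_divergence = trait_divergence,
                 trait_cor = trait_cor, seed = as.integer(seed)),
            class = "sim_config")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Hierarchical (Balding-Nichols style) subpopulation frequencies: a draw
# from Dirichlet(base * (1 - d) / d) has mean `base` and per-allele variance
# d * b * (1 - b), so `d` acts as the Fst-like divergence between
# subpopulations; d = 0 collapses to the shared base exactly.
rsubpop_freqs <- function(base, divergence) {
  if (divergence == 0) return(base)
  g <- stats::rgamma(length(base), shape = base * (1 - divergence) / divergence)
  if (sum(g) == 0) {  # guard against all-zero gamma draws at tiny shapes
    g[sample.int(length(g), 1)] <- 1
  }
  g / sum(g)
}

#' Simulate a germplasm panel with known structure
#'
#' Draws a panel under the generator's model: accessions are assigned to
#' region strata and (independently) to subpopulations; traits come from
#' per-subpopulation correlated normal distributions clipped at zero
#' (every descriptor is a nonnegative quantity), with subpopulation means
#' split `trait_divergence` SDs apart around the configured means; each locus
#' carries one band per accession (homozygote model for a predominantly
#' selfing species), sampled from the accession's subpopulation band
#' frequencies. Per locus, a shared base frequency vector is drawn from a
#' symmetric Dirichlet; each subpopulation's frequencies are then drawn
#' from a Dirichlet centered on the base with concentration
#' `(1 - divergence) / divergence`, so `divergence` is the Fst-like
#' between-subpopulation variance share.
#'
#' @param cfg a [simulation_config()]
#' @return list with elements `panel` (a [germplasm_panel]) and `truth`
#'   (list: `subpop` named assignment vector, `locus_frequencies` per-
#'   subpopulation list of per-locus frequency vectors)
#' @export
simulate_panel <- function(cfg) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(simulation_config, cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_accessions
    ids <- sprintf("ACC%05d", seq_len(n))
    regions <- sample(names(cfg$region_weights), n, replace = TRUE,
                      prob = cfg$region_weights)
    ctry_pool <- default_region_countries()
    country <- vapply(regions, function(r) {
      pool <- ctry_pool[[r]] %||% r
      pool[sample.int(length(pool), 1L)]
    }, "")
    subpop <- sample.int(cfg$n_subpops, n, replace = TRUE)

    shared <- is.data.frame(cfg$trait_params)
    tp <- if (shared) rep(list(cfg$trait_params), cfg$n_subpops)
          else cfg$trait_params
    codes <- tp[[1]]$code
    K <- length(codes)
    S <- cfg$n_subpops
    # centered unit-variance subpopulation contrasts so that splitting the
    # configured variance between and within subpops leaves the whole-panel
    # mean and variance at their configured values
    ctr <- if (S > 1) {
      raw <- seq_len(S) - (S + 1) / 2
      raw / sqrt(mean(raw^2))
    } else 0
    traits <- matrix(NA_real_, n, K, dimnames = list(ids, codes))
    chol_cor <- chol(cfg$trait_cor)
    for (s in seq_len(S)) {
      rows <- which(subpop == s)
      if (!length(rows)) next
      mu <- tp[[s]]$mean
      sd <- sqrt(tp[[s]]$var)
      if (shared && S > 1) {
        mu <- mu + cfg$trait_divergence * sd * ctr[s]
        sd <- sd * sqrt(1 - cfg$trait_divergence^2)
      }
      z <- matrix(stats::rnorm(length(rows) * K), ncol = K) %*% chol_cor
      x <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
      traits[rows, ] <- pmax(x, 0)
    }

    locus_names <- sprintf("SSR%02d", seq_len(cfg$n_loci))
    r <- cfg$alleles_per_locus_range
    n_alleles <- sample(seq(r[1], r[2]), cfg$n_loci, replace = TRUE)
    loci <- stats::setNames(lapply(n_alleles, function(k) {
      sprintf("B%02d", seq_len(k))
    }), locus_names)

    freqs <- vector("list", cfg$n_subpops)
    for (s in seq_len(cfg$n_subpops)) freqs[[s]] <- vector("list", cfg$n_loci)
    for (l in seq_len(cfg$n_loci)) {
      k <- n_alleles[l]
      base <- rdirichlet1(k)
      for (s in seq_len(cfg$n_subpops)) {
        p <- rsubpop_freqs(base, cfg$divergence)
        freqs[[s]][[l]] <- stats::setNames(p, loci[[l]])
      }
    }
    for (s in seq_len(cfg$n_subpops)) names(freqs[[s]]) <- locus_names

    bands <- matrix(0L, n, sum(n_alleles),
                    dimnames = list(ids, paste(rep(locus_names, n_alleles),
                                               unlist(loci), sep = ":")))
    offs <- c(0L, cumsum(n_alleles))
    for (l in seq_len(cfg$n_loci)) {
      for (s in seq_len(cfg$n_subpops)) {
        rows <- which(subpop == s)
        if (!length(rows)) next
        pick <- sample.int(n_alleles[l], length(rows), replace = TRUE,
                           prob = freqs[[s]][[l]])
        bands[cbind(rows, offs[l] + pick)] <- 1L
      }
    }

    passport <- data.frame(id = ids, country = unname(country),
                           region = regions, stringsAsFactors = FALSE)
    dsc <- mungbean_descriptors()
    if (all(codes %in% dsc$code)) {
      dsc <- dsc[match(codes, dsc$code), , drop = FALSE]
    } else {
      dsc <- data.frame(code = codes, label = codes, units = "",
                        n_classes = 10L, stringsAsFactors = FALSE)
    }
    panel <- germplasm_panel(passport, traits, bands, descriptors = dsc,
                             loci = loci)
    truth <- list(subpop = stats::setNames(subpop, ids),
                  locus_frequencies = freqs)
    list(panel = panel, truth = truth)
  })
}

#' Mask random locus cells as missing
#'
#' Independently sets each accession-by-locus cell to missing (all band
#' columns of the locus become `NA`) with probability `missing_rate`,
#' emulating genotyping dropout. The input panel is not modified.
#'
#' @param panel a [germplasm_panel]
#' @param missing_rate probability in `[0, 1)`
#' @param seed integer seed
#' @return a new [germplasm_panel] with masked cells
#' @export
simulate_band_noise <- function(panel, missing_rate, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (missing_rate == 0) return(panel)
  with_seed(seed, {
    n <- n_accessions(panel)
    L <- names(panel$loci)
    mask <- matrix(stats::runif(n * length(L)) < missing_rate, n, length(L))
    bands <- panel$bands
    for (j in seq_along(L)) {
      cols <- which(panel$band_locus == L[j])
      rows <- which(mask[, j])
      if (length(rows)) bands[rows, cols] <- NA_integer_
    }
    germplasm_panel(panel$passport, panel$traits, bands,
                    panel$descriptors, panel$loci)
  })
}
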