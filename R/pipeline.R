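# Deterministic per-stage seed derived from the global seed and the stage
# name, so adding stages never shifts existing random streams. Kept below
# 2^31 to stay a valid R integer seed.
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483647)
}

#' Default pipeline configuration
#'
#' @param out_dir run directory
#' @param seed global seed; every stochastic stage derives its own seed
#'   from it and its stage name
#' @return nested configuration list accepted by [run_pipeline()]
#' @export
default_pipeline_config <- function(out_dir = "germcore_run", seed = 42L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    simulate = list(n_accessions = 1000L, n_loci = 20L,
                    alleles_per_locus_range = c(3L, 13L),
                    n_subpops = 2L, divergence = 0.3),
    load = NULL,  # list(trait_path=, band_path=, passport_path=) to skip simulation
    core = list(fraction = 0.2, target_clusters = NULL, cut_height = NULL),
    minicore = list(fraction = 0.2, weight_mr = 0.7, weight_shannon = 0.3,
                    steps = 1500L, n_replicas = 3L),
    validation = list(mantel_n_perm = 199L, mantel_max_n = 200L)
  )
}

pipeline_write_manifest_line <- function(con, stage, info) {
  writeLines(jsonlite::toJSON(c(list(stage = stage), info),
                              auto_unbox = TRUE, digits = 10), con)
}

#' Run the full core / mini-core workflow
#'
#' Executes simulate (or load) -> core selection -> core validation ->
#' mini-core optimization plus the two baseline mini cores -> strategy
#' comparison, writing panel CSVs, selection files, per-locus and
#' per-descriptor reports, Newick dendrograms, the optimizer trace and a
#' JSON-lines run manifest into the run directory. The manifest is a pure
#' function of configuration and seed.
#'
#' @param config configuration list as produced by
#'   [default_pipeline_config()], or a path to a YAML file with the same
#'   structure
#' @return invisibly, the run directory path
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  cfg <- utils::modifyList(base, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(cfg$out_dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  pth <- function(f) file.path(cfg$out_dir, f)
  stage <- "setup"
  tryCatch({
    # --- panel ---
    if (!is.null(cfg$load)) {
      stage <- "load"
      panel <- read_panel(cfg$load$trait_path, cfg$load$band_path,
                          cfg$load$passport_path)
      sim_seed <- NA_integer_
    } else {
      stage <- "simulate"
      sim_seed <- stage_seed(cfg$seed, "simulate")
      sim <- simulate_panel(do.call(simulation_config,
                                    c(cfg$simulate, list(seed = sim_seed))))
      panel <- sim$panel
    }
    write_panel(panel, pth("traits.csv"), pth("bands.csv"),
                pth("passport.csv"))
    pipeline_write_manifest_line(con, "panel", list(
      seed = sim_seed, n_accessions = n_accessions(panel),
      n_loci = length(panel$loci), n_bands = ncol(panel$bands)))

    # --- core ---
    stage <- "core"
    core_seed <- stage_seed(cfg$seed, "core")
    core <- build_core(panel, fraction = cfg$core$fraction,
                       cut_height = cfg$core$cut_height,
                       target_clusters = cfg$core$target_clusters,
                       seed = core_seed)
    write_selection(core, pth("core_selection.csv"))
    pipeline_write_manifest_line(con, "core", list(
      seed = core_seed, n_selected = length(core),
      fraction = cfg$core$fraction))

    # --- core validation ---
    stage <- "validate_core"
    val_seed <- stage_seed(cfg$seed, "validate_core")
    rep_core <- validate_core_representativeness(
      panel, core, mantel_n_perm = cfg$validation$mantel_n_perm,
      mantel_max_n = cfg$validation$mantel_max_n, seed = val_seed)
    write_comparison_report(rep_core, pth("core_validation.csv"))
    pipeline_write_manifest_line(con, "validate_core", list(
      seed = val_seed,
      max_rel_mean_diff_pct = max(rep_core$traits$rel_mean_diff_pct),
      mantel_r = if (is.null(rep_core$mantel)) NA else rep_core$mantel$r))

    # --- diversity reports on the core ---
    stage <- "diversity"
    div <- count_alleles_genotypes(panel, core)
    utils::write.csv(div, pth("core_marker_diversity.csv"),
                     row.names = FALSE, quote = FALSE)
    tr <- summary_stats(panel, core)
    utils::write.csv(tr, pth("core_trait_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    pipeline_write_manifest_line(con, "diversity", list(
      total_alleles = attr(div, "total_alleles"),
      total_multilocus_genotypes = attr(div, "total_multilocus_genotypes")))

    # --- trees of the core ---
    stage <- "trees"
    cpanel <- subset_panel(panel, core)
    ph_tree <- upgma(standardized_euclidean(cpanel))
    mk_tree <- upgma(modified_rogers_distance(cpanel))
    write_newick(ph_tree, pth("core_phenotype.nwk"))
    write_newick(mk_tree, pth("core_marker.nwk"))
    pipeline_write_manifest_line(con, "trees", list(
      phenotype_root_height = max(ph_tree$height),
      marker_root_height = max(mk_tree$height)))

    # --- mini cores ---
    stage <- "minicore"
    mc_seed <- stage_seed(cfg$seed, "minicore")
    mcfg <- minicore_config(weight_mr = cfg$minicore$weight_mr,
                            weight_shannon = cfg$minicore$weight_shannon,
                            target_fraction = cfg$minicore$fraction,
                            steps = cfg$minicore$steps,
                            n_replicas = cfg$minicore$n_replicas,
                            seed = mc_seed)
    opt <- build_minicore(cpanel, mcfg)
    mc_cluster <- minicore_by_cluster_sampling(
      cpanel, tree = mk_tree, fraction = cfg$minicore$fraction,
      seed = stage_seed(cfg$seed, "minicore_cluster"))
    mc_region <- minicore_by_region(
      cpanel, fraction = cfg$minicore$fraction,
      seed = stage_seed(cfg$seed, "minicore_region"))
    write_selection(opt$selection, pth("minicore_optimizer.csv"))
    write_selection(mc_cluster, pth("minicore_cluster.csv"))
    write_selection(mc_region, pth("minicore_region.csv"))
    utils::write.csv(opt$trace, pth("minicore_trace.csv"),
                     row.names = FALSE, quote = FALSE)
    pipeline_write_manifest_line(con, "minicore", list(
      seed = mc_seed, n_selected = length(opt$selection),
      objective = opt$selection$objective))

    # --- strategy comparison ---
    stage <- "compare"
    cmp <- compare_minicores(cpanel, list(
      core = seq_len(n_accessions(cpanel)),
      minicore_opt = opt$selection,
      minicore_cluster = mc_cluster,
      minicore_region = mc_region))
    utils::write.csv(cmp, pth("minicore_comparison.csv"),
                     row.names = FALSE, quote = FALSE)
    means <- attr(cmp, "means")
    pipeline_write_manifest_line(con, "compare",
                                 as.list(round(means, 6)))
  }, error = function(e) {
    file.create(pth(".failed"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(cfg$out_dir)
}
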