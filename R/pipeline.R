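#' Pipeline run configuration
#'
#' Collects every threshold and seed of the pipeline with the standard
#' defaults: rarefaction depths of 40,000 (bacteria) and 39,000 (fungi)
#' reads, network gates `|rho| >= 0.65` and `q < 0.05`, bacterial
#' occurrence >= 5 samples and mean relative abundance >= 0.05%, fungal
#' mean relative abundance >= 0.001%, top-10% core fraction, and 5,000
#' bootstrap iterations.
#'
#' @param counts_bacteria,counts_fungi,meta,tree_bacteria,tree_fungi,functions_bacteria,functions_fungi,pollen
#'   input file paths (all optional when `simulate = TRUE`).
#' @param simulate when `TRUE`, inputs are generated with [synth_spec()]
#'   defaults instead of read from files.
#' @param depth_bacteria,depth_fungi rarefaction depths (reads).
#' @param rho_min,q_max network gates.
#' @param occurrence_min,bacteria_mean_ra_min,fungi_mean_ra_min genus
#'   filters.
#' @param core_top_frac core centrality cutoff fraction.
#' @param bootstrap_iters bootstrap iterations for the species-level
#'   Spearman.
#' @param n_perm PERMANOVA permutations.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(counts_bacteria = NULL, counts_fungi = NULL,
                       meta = NULL, tree_bacteria = NULL, tree_fungi = NULL,
                       functions_bacteria = NULL, functions_fungi = NULL,
                       pollen = NULL, simulate = is.null(counts_bacteria),
                       depth_bacteria = 40000L, depth_fungi = 39000L,
                       rho_min = 0.65, q_max = 0.05,
                       occurrence_min = 5L,
                       bacteria_mean_ra_min = 5e-4,
                       fungi_mean_ra_min = 1e-5,
                       core_top_frac = 0.10,
                       bootstrap_iters = 5000L, n_perm = 999L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!is.null(cfg$rho_min) && (cfg$rho_min <= 0 || cfg$rho_min > 1))
    stop("rho_min must lie in (0, 1]")
  if (cfg$q_max <= 0 || cfg$q_max > 1) stop("q_max must lie in (0, 1]")
  for (nm in c("depth_bacteria", "depth_fungi", "occurrence_min",
               "bacteria_mean_ra_min", "fungi_mean_ra_min",
               "core_top_frac", "bootstrap_iters", "n_perm"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (cfg$core_top_frac > 1) stop("core_top_frac must be <= 1")
  if (!cfg$simulate) {
    for (nm in c("counts_bacteria", "counts_fungi", "meta")) {
      if (is.null(cfg[[nm]])) stop("missing required input: ", nm)
      if (!file.exists(cfg[[nm]])) stop("input file not found: ", cfg[[nm]])
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> diversity -> networks (per group and
#' mode) -> core contribution -> visitation statistics, writing every stage
#' output as TSV plus a provenance manifest (versions, seeds, thresholds,
#' input checksums) under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return named list of stage results, invisibly; side effect: files under
#'   `out_dir` and `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list()
  if (config$simulate) {
    spec <- synth_spec(seed = config$seed)
    sim_dir <- file.path(out_dir, "simulated_inputs")
    paths <- simulate_dataset(spec, sim_dir)
    config$counts_bacteria <- paths[["bacteria"]]
    config$counts_fungi <- paths[["fungi"]]
    config$meta <- paths[["meta"]]
    config$tree_bacteria <- paths[["tree_bacteria"]]
    config$tree_fungi <- paths[["tree_fungi"]]
    config$functions_bacteria <- paths[["fun_bacteria"]]
    config$functions_fungi <- paths[["fun_fungi"]]
    config$pollen <- paths[["pollen"]]
  }
  bact <- read_count_table(config$counts_bacteria, "bacteria", "genus")
  fung <- read_count_table(config$counts_fungi, "fungi", "genus")
  meta <- read_sample_frame(config$meta)
  groups <- assign_groups(meta)
  results <- list()

  # --- diversity ---------------------------------------------------------
  depths <- c(bacteria = config$depth_bacteria, fungi = config$depth_fungi)
  trees <- list(
    bacteria = if (!is.null(config$tree_bacteria))
      ape::read.tree(config$tree_bacteria),
    fungi = if (!is.null(config$tree_fungi))
      ape::read.tree(config$tree_fungi))
  for (dm in c("bacteria", "fungi")) {
    ct <- if (dm == "bacteria") bact else fung
    alpha <- alpha_diversity(ct, tree = trees[[dm]], depth = depths[[dm]],
                             seed = config$seed)
    write.table(alpha, file.path(out_dir, paste0("alpha_", dm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    m <- meta[match(alpha$sample_id, meta$sample_id), ]
    aov_tabs <- lapply(intersect(c("chao1", "shannon", "pd"), names(alpha)),
                       function(ix) cbind(index = ix,
                                          two_way_anova(alpha[[ix]], m)))
    aovs <- do.call(rbind, aov_tabs)
    write.table(aovs, file.path(out_dir, paste0("anova_", dm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ra <- to_relative_abundance(ct)
    bc <- bray_curtis(ra)
    perm <- permanova(bc, groups[sample_ids(ct)], n_perm = config$n_perm,
                      seed = config$seed)
    write.table(perm, file.path(out_dir, paste0("permanova_", dm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results[[paste0("alpha_", dm)]] <- alpha
    results[[paste0("permanova_", dm)]] <- perm
  }

  # --- networks and core taxa -------------------------------------------
  fun_tabs <- list(
    bacteria = if (!is.null(config$functions_bacteria))
      read_function_table(config$functions_bacteria),
    fungi = if (!is.null(config$functions_fungi))
      read_function_table(config$functions_fungi))
  ras <- list(bacteria = to_relative_abundance(bact),
              fungi = to_relative_abundance(fung))
  topo_rows <- list()
  core_rows <- list()
  for (grp in unique(groups)) {
    smp <- names(groups)[groups == grp]
    for (mode in c("bacteria", "fungi", "cross_domain")) {
      net <- tryCatch(
        group_network(bact, fung, meta, group = grp, mode = mode,
                      rho_min = config$rho_min, q_max = config$q_max,
                      min_occurrence = config$occurrence_min),
        error = function(e) NULL)
      if (is.null(net)) next
      net <- detect_modules(net, seed = config$seed)
      write_edge_list(net, file.path(out_dir,
                                     sprintf("edges_%s_%s.tsv", grp, mode)))
      topo_rows[[paste(grp, mode)]] <- topology(net)
      if (mode == "cross_domain") {
        core <- suppressWarnings(identify_core(net,
                                               config$core_top_frac))
        for (dm in c("bacteria", "fungi")) {
          core_dm <- intersect(core, taxon_ids(if (dm == "bacteria") bact
                                               else fung))
          cc <- core_contribution(core_dm, ras[[dm]], fun_tabs[[dm]], smp)
          core_rows[[paste(grp, dm)]] <-
            cbind(group = grp, domain = dm, cc,
                  core_genera = paste(core_dm, collapse = ","))
        }
      }
    }
  }
  topo <- do.call(rbind, topo_rows)
  write.table(topo, file.path(out_dir, "topology.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  core_report <- do.call(rbind, core_rows)
  write.table(core_report, file.path(out_dir, "core_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  results$topology <- topo
  results$core_report <- core_report

  # --- visitation --------------------------------------------------------
  if (!is.null(config$pollen)) {
    pollen <- read.delim(config$pollen, stringsAsFactors = FALSE)
    rates <- do.call(rbind, lapply(unique(pollen$species), function(sp)
      remaining_rate(pollen, sp)))
    vis <- tukey_anova(rates$rate, rates$species)
    vis_tab <- data.frame(
      species = names(vis$letters),
      mean_rate = tapply(rates$rate, rates$species,
                         mean)[names(vis$letters)],
      se_rate = tapply(rates$rate, rates$species, function(v)
        sd(v) / sqrt(length(v)))[names(vis$letters)],
      significance = unname(vis$letters))
    write.table(vis_tab, file.path(out_dir, "remaining_rates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$remaining_rates <- vis_tab
    results$visitation_anova <- vis
  }

  manifest <- list(
    package_version = as.character(packageVersion("pollenet")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    thresholds = config[c("depth_bacteria", "depth_fungi", "rho_min",
                          "q_max", "occurrence_min",
                          "bacteria_mean_ra_min", "fungi_mean_ra_min",
                          "core_top_frac", "bootstrap_iters", "n_perm")],
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("counts_bacteria", "counts_fungi", "meta",
                      "tree_bacteria", "tree_fungi", "functions_bacteria",
                      "functions_fungi", "pollen")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
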