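#' Specification of a synthetic pollen-microbiome dataset
#'
#' Describes a study-shaped dataset: a factorial design of host species
#' (self- and cross-pollinated) by insect-exclusion treatment with a fixed
#' number of replicates, two microbial domains with log-normal genus
#' abundance profiles, planted within-block latent correlations (the ground
#' truth for network-edge recovery), a planted high-abundance core genus set
#' in one group (ground truth for core-contribution recovery), and
#' per-species pollen-count parameters expressed as target remaining-rate
#' means/SEs.
#'
#' Counts are generated from a latent Gaussian copula: per sample, genus
#' log-intensities are drawn with block covariance from `planted_blocks`
#' plus genus-specific species and treatment shifts, exponentiated, and read
#' counts are drawn multinomially at a uniform random library size.  The
#' copula construction makes pairwise rank correlations directly plantable,
#' which matters because Spearman correlation is the pipeline's edge
#' statistic.
#'
#' @param n_reps replicates per species x treatment (default 5; the default
#'   design is 4 species x 2 treatments x 5 replicates = 40 samples).
#' @param species host species labels; `pollination` maps each to
#'   `"self"` or `"cross"`.
#' @param pollination named character vector, one entry per species.
#' @param n_taxa named vector, genera per domain.  Defaults are scaled-down
#'   study-shaped sizes (150 bacterial, 60 fungal genera).
#' @param library_size two-element range of per-sample read depth, sampled
#'   uniformly; the default straddles typical rarefaction depths
#'   (39,000-90,000 reads).
#' @param block_size,n_blocks,block_rho planted correlation blocks per
#'   domain: `n_blocks` disjoint blocks of `block_size` genera whose latent
#'   log-intensities share a common factor giving pairwise latent
#'   correlation `block_rho`.
#' @param core_target,core_size,core_group,core_domain,core_sample_sd the
#'   planted core set: `core_size` genera of `core_domain` whose summed
#'   relative abundance in samples of `core_group` is rescaled to an
#'   expected share of `core_target` (per-sample shares jitter around the
#'   target with SD `core_sample_sd` on the proportion scale).
#' @param effect_species,effect_treatment named per-domain SDs (log scale)
#'   of genus-specific species and treatment shifts; fungal defaults exceed
#'   bacterial ones so the fungal community separates more strongly by
#'   group, as in real pollen data.
#' @param pollen_params data.frame with columns `species`, `bagging_mean`
#'   (grains), `rate_mean` and `rate_se` (target remaining-rate mean and SE,
#'   percent).  The default targets are the field-observed remaining rates
#'   of the four crops (CA 64.94 +/- 1.01, SM 90.04 +/- 1.67, LA
#'   83.01 +/- 2.87, MC 97.23 +/- 0.59).
#' @param bagging_cv coefficient of variation of pollen grain counts in the
#'   bagging arm (the field data report no within-species bagging variance;
#'   5 percent is used as a realistic default).
#' @param seed integer seed making every generator deterministic.
#'
#' @return an object of class `synth_spec`.
#' @seealso [generate_counts()], [generate_tree()],
#'   [generate_pollen_counts()], [generate_function_table()]
#' @export
synth_spec <- function(n_reps = 5L,
                       species = c("CA", "SM", "LA", "MC"),
                       pollination = c(CA = "self", SM = "self",
                                       LA = "cross", MC = "cross"),
                       n_taxa = c(bacteria = 150L, fungi = 60L),
                       library_size = c(39000L, 90000L),
                       block_size = c(bacteria = 6L, fungi = 5L),
                       n_blocks = c(bacteria = 3L, fungi = 2L),
                       block_rho = 0.9,
                       core_target = 0.85,
                       core_size = 12L,
                       core_group = "Cross_open",
                       core_domain = "fungi",
                       core_sample_sd = 0.08,
                       effect_species = c(bacteria = 0.6, fungi = 2.0),
                       effect_treatment = c(bacteria = 0.3, fungi = 1.0),
                       pollen_params = NULL,
                       bagging_cv = 0.05,
                       seed = 1L) {
  if (is.null(pollen_params))
    pollen_params <- data.frame(
      species = c("CA", "SM", "LA", "MC"),
      bagging_mean = c(24000, 18000, 52000, 31000),
      rate_mean = c(64.94, 90.04, 83.01, 97.23),
      rate_se = c(1.01, 1.67, 2.87, 0.59))
  spec <- list(n_reps = as.integer(n_reps), species = species,
               pollination = pollination, n_taxa = n_taxa,
               library_size = library_size, block_size = block_size,
               n_blocks = n_blocks, block_rho = block_rho,
               core_target = core_target, core_size = as.integer(core_size),
               core_group = core_group, core_domain = core_domain,
               core_sample_sd = core_sample_sd,
               effect_species = effect_species,
               effect_treatment = effect_treatment,
               pollen_params = pollen_params, bagging_cv = bagging_cv,
               seed = as.integer(seed))
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
}

#' @rdname synth_spec
#' @param spec a `synth_spec`.
#' @export
validate_synth_spec <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$n_reps < 1L) stop("n_reps must be >= 1")
  if (!all(spec$species %in% names(spec$pollination)))
    stop("every species needs a pollination entry")
  if (!all(spec$pollination %in% c("self", "cross")))
    stop("pollination entries must be 'self' or 'cross'")
  if (spec$core_target <= 0 || spec$core_target >= 1)
    stop("core_target must lie in (0, 1)")
  if (abs(spec$block_rho) >= 1) stop("block_rho must lie in (-1, 1)")
  if (any(spec$library_size < 1) || diff(spec$library_size) < 0)
    stop("library_size must be an increasing positive range")
  if (any(spec$pollen_params$bagging_mean <= 0) ||
      any(spec$pollen_params$rate_mean <= 0))
    stop("pollen means must be positive")
  spec
}

# Deterministic taxon names and plausible lineages per domain.
.synth_taxa <- function(domain, n) {
  phyla <- if (domain == "bacteria") {
    c("Proteobacteria", "Firmicutes", "Bacteroidota", "Actinobacteriota",
      "Acidobacteriota")
  } else {
    c("Ascomycota", "Basidiomycota", "Mortierellomycota", "Chytridiomycota")
  }
  tag <- if (domain == "bacteria") "B" else "F"
  king <- if (domain == "bacteria") "k__Bacteria" else "k__Fungi"
  ids <- sprintf("g%s%03d", tag, seq_len(n))
  ph <- phyla[(seq_len(n) - 1L) %% length(phyla) + 1L]
  tax <- sprintf("%s;p__%s;c__C%s;o__O%s;f__F%s;g__Genus_%s%03d",
                 king, ph, tag, tag, tag, tag, seq_len(n))
  list(ids = ids, taxonomy = tax)
}

#' Generate synthetic bacterial and fungal count tables
#'
#' Draws the full factorial dataset described by a [synth_spec()]: genus
#' log-intensities from the latent Gaussian copula (block covariance,
#' species/treatment shifts), planted-core rescaling in the target group,
#' and multinomial read sampling per sample.  Deterministic under
#' `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return a list with elements `bacteria` and `fungi` ([count_table]s at
#'   genus level), `meta` (sample metadata data.frame) and `truth`
#'   (planted block membership and core genus ids per domain).
#' @export
generate_counts <- function(spec) {
  validate_synth_spec(spec)
  set.seed(spec$seed)
  meta <- expand.grid(replicate = seq_len(spec$n_reps),
                      treatment = c("open", "bagging"),
                      species = spec$species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$pollination <- unname(spec$pollination[meta$species])
  meta$sample_id <- sprintf("%s_%s_%d", meta$species, meta$treatment,
                            meta$replicate)
  meta <- meta[, c("sample_id", "species", "treatment", "pollination",
                   "replicate")]
  groups <- assign_groups(meta)
  n_samp <- nrow(meta)

  out <- list()
  truth <- list()
  for (domain in c("bacteria", "fungi")) {
    n <- spec$n_taxa[[domain]]
    tax <- .synth_taxa(domain, n)
    # base abundance profile: geometric decay over ranked genera + jitter
    mu <- seq(log(2000), log(0.5), length.out = n) + rnorm(n, sd = 0.3)
    # planted blocks sit among moderately abundant genera so multinomial
    # noise does not swamp the planted rank correlation
    nb <- spec$n_blocks[[domain]]
    bs <- spec$block_size[[domain]]
    blocks <- split(seq_len(nb * bs) + 4L, rep(seq_len(nb), each = bs))
    block_of <- integer(n)
    for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
    # genus-specific group shifts (log scale)
    sp_shift <- matrix(rnorm(n * length(spec$species),
                             sd = spec$effect_species[[domain]]),
                       nrow = n, dimnames = list(NULL, spec$species))
    tr_shift <- rnorm(n, sd = spec$effect_treatment[[domain]])
    # core set: planted among abundant non-block genera when this domain
    # carries the core
    core_idx <- integer(0)
    if (domain == spec$core_domain) {
      free <- setdiff(seq_len(n), unlist(blocks))
      core_idx <- free[seq_len(min(spec$core_size, length(free)))]
    }
    counts <- matrix(0L, nrow = n, ncol = n_samp,
                     dimnames = list(tax$ids, meta$sample_id))
    libs <- round(runif(n_samp, spec$library_size[1], spec$library_size[2]))
    for (s in seq_len(n_samp)) {
      z <- rnorm(n)
      for (b in seq_along(blocks)) {
        f <- rnorm(1L)
        idx <- blocks[[b]]
        z[idx] <- sqrt(spec$block_rho) * f +
          sqrt(1 - spec$block_rho) * z[idx]
      }
      lat <- mu + sp_shift[, meta$species[s]] +
        tr_shift * (meta$treatment[s] == "open") + z
      lam <- exp(lat)
      if (length(core_idx) && groups[[meta$sample_id[s]]] == spec$core_group) {
        share <- min(max(rnorm(1L, spec$core_target, spec$core_sample_sd),
                         0.02), 0.98)
        cur <- sum(lam[core_idx]) / sum(lam)
        f <- share * (1 - cur) / (cur * (1 - share))
        if (!is.finite(f) || f <= 0)
          stop("infeasible core target for sample ", meta$sample_id[s])
        lam[core_idx] <- lam[core_idx] * f
      }
      counts[, s] <- as.integer(rmultinom(1L, size = libs[s],
                                          prob = lam / sum(lam)))
    }
    out[[domain]] <- count_table(counts, taxonomy = tax$taxonomy,
                                 domain = domain, level = "genus")
    truth[[domain]] <- list(
      blocks = lapply(blocks, function(i) tax$ids[i]),
      block_of = setNames(block_of, tax$ids),
      core = tax$ids[core_idx])
  }
  list(bacteria = out$bacteria, fungi = out$fungi, meta = meta,
       truth = truth)
}

#' Generate a random rooted phylogeny over a taxon set
#'
#' A coalescent-style random rooted tree (via [ape::rcoal()]) with positive
#' branch lengths, or a unit-branch star tree, suitable as the tree input of
#' Faith's PD.
#'
#' @param taxon_ids tip labels (>= 2).
#' @param seed integer seed.
#' @param type `"coalescent"` (default) or `"star"` (all tips attached to
#'   the root with branch length 1).
#' @return an [ape::phylo] rooted tree.
#' @export
generate_tree <- function(taxon_ids, seed = 1L,
                          type = c("coalescent", "star")) {
  type <- match.arg(type)
  n <- length(taxon_ids)
  if (n < 2L) stop("need at least 2 taxa to build a tree")
  set.seed(seed)
  if (type == "star") {
    tr <- ape::stree(n, type = "star", tip.label = taxon_ids)
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else {
    tr <- ape::rcoal(n, tip.label = taxon_ids)
  }
  tr
}

#' Generate per-replicate pollen grain counts
#'
#' Draws grain counts per species, treatment and replicate so that the
#' remaining rate (open grains / mean bagging grains x 100) has the target
#' mean and SE stored in the spec's `pollen_params`.  Normal draws are
#' truncated at zero; deterministic under seed.
#'
#' @param spec a [synth_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return data.frame with columns `species`, `treatment`, `replicate`,
#'   `grains`.
#' @export
generate_pollen_counts <- function(spec, seed = spec$seed) {
  validate_synth_spec(spec)
  set.seed(seed)
  pp <- spec$pollen_params
  rows <- lapply(seq_len(nrow(pp)), function(i) {
    B <- pp$bagging_mean[i]
    bag <- pmax(rnorm(spec$n_reps, B, spec$bagging_cv * B), 0)
    open_mean <- B * pp$rate_mean[i] / 100
    open_sd <- B * pp$rate_se[i] * sqrt(spec$n_reps) / 100
    opn <- pmax(rnorm(spec$n_reps, open_mean, open_sd), 0)
    data.frame(species = pp$species[i],
               treatment = rep(c("open", "bagging"), each = spec$n_reps),
               replicate = rep(seq_len(spec$n_reps), 2L),
               grains = c(opn, bag))
  })
  do.call(rbind, rows)
}

#' Generate a predicted-function table for a genus set
#'
#' Emulates genus-level functional prediction output.  Bacterial genera get
#' a weight profile over pathway labels summing to 1 per genus (Dirichlet
#' draws); fungal genera are each assigned a single trophic mode
#' (pathotroph/saprotroph/symbiotroph/unassigned) with weight 1, so a fungal
#' genus's functional relative abundance equals its taxonomic relative
#' abundance — the identity observed for guild-type predictions.
#'
#' @param taxon_ids genus identifiers.
#' @param domain `"bacteria"` or `"fungi"`.
#' @param n_functions number of pathway labels for bacteria.
#' @param seed integer seed.
#' @return data.frame with columns `taxon_id`, `function_id`, `value`
#'   (class `function_table`); per-genus values sum to 1.
#' @export
generate_function_table <- function(taxon_ids,
                                    domain = c("bacteria", "fungi"),
                                    n_functions = 20L, seed = 1L) {
  domain <- match.arg(domain)
  set.seed(seed)
  if (length(taxon_ids) == 0L) {
    out <- data.frame(taxon_id = character(0), function_id = character(0),
                      value = numeric(0))
  } else if (domain == "bacteria") {
    fn <- sprintf("pathway_%02d", seq_len(n_functions))
    w <- matrix(rgamma(length(taxon_ids) * n_functions, shape = 0.5),
                nrow = length(taxon_ids))
    w <- w / rowSums(w)
    out <- data.frame(taxon_id = rep(taxon_ids, times = n_functions),
                      function_id = rep(fn, each = length(taxon_ids)),
                      value = as.vector(w))
  } else {
    modes <- c("pathotroph", "saprotroph", "symbiotroph", "unassigned")
    out <- data.frame(taxon_id = taxon_ids,
                      function_id = sample(modes, length(taxon_ids),
                                           replace = TRUE),
                      value = 1)
  }
  class(out) <- c("function_table", "data.frame")
  out
}

#' Read a genus-level function table from TSV
#'
#' @param path TSV with columns `taxon_id`, `function_id`, `value`.
#' @return a `function_table` data.frame; negative values are rejected.
#' @export
read_function_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "function_id", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("function table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$value < 0)) stop("function values must be non-negative")
  class(df) <- c("function_table", "data.frame")
  df
}

#' Write all synthetic fixture files for a dataset
#'
#' Runs the generators and writes the count tables, metadata, tree,
#' function tables and pollen counts in the pipeline's interchange formats.
#'
#' @param spec a [synth_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
simulate_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- generate_counts(spec)
  paths <- c(bacteria = file.path(dir, "bacteria_genus.tsv"),
             fungi = file.path(dir, "fungi_genus.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             tree_bacteria = file.path(dir, "bacteria.nwk"),
             tree_fungi = file.path(dir, "fungi.nwk"),
             fun_bacteria = file.path(dir, "bacteria_functions.tsv"),
             fun_fungi = file.path(dir, "fungi_functions.tsv"),
             pollen = file.path(dir, "pollen_counts.tsv"))
  write_count_table(dat$bacteria, paths[["bacteria"]])
  write_count_table(dat$fungi, paths[["fungi"]])
  write.table(dat$meta, paths[["meta"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  ape::write.tree(generate_tree(taxon_ids(dat$bacteria), seed = spec$seed),
                  paths[["tree_bacteria"]])
  ape::write.tree(generate_tree(taxon_ids(dat$fungi), seed = spec$seed + 1L),
                  paths[["tree_fungi"]])
  fb <- generate_function_table(taxon_ids(dat$bacteria), "bacteria",
                                seed = spec$seed)
  ff <- generate_function_table(taxon_ids(dat$fungi), "fungi",
                                seed = spec$seed)
  write.table(fb, paths[["fun_bacteria"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ff, paths[["fun_fungi"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(generate_pollen_counts(spec), paths[["pollen"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
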