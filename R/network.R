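#' Filter genera for network construction
#'
#' Applies the domain-specific prevalence/abundance filters used before
#' correlation analysis.  Bacterial genera are retained when they occur
#' (nonzero count) in at least `min_occurrence` of the group's samples and
#' have mean relative abundance >= `min_mean_ra` over those samples.
#' Fungal communities are sparser and lower-abundance, so only the mean
#' relative-abundance gate (default 1e-5) is applied.
#'
#' @param r a `rel_abundance_table` (see [to_relative_abundance()]).
#' @param samples sample ids of the group the network is built for.
#' @param domain `"bacteria"` or `"fungi"` (defaults to the table's own
#'   domain tag).
#' @param min_occurrence bacterial occurrence threshold (samples).
#' @param min_mean_ra mean relative-abundance threshold; defaults to 5e-4
#'   for bacteria and 1e-5 for fungi.
#' @return character vector of retained genus ids.
#' @export
filter_genera <- function(r, samples, domain = r$domain,
                          min_occurrence = 5L, min_mean_ra = NULL) {
  stopifnot(inherits(r, "rel_abundance_table"))
  samples <- intersect(samples, colnames(r$values))
  if (length(samples) == 0L) stop("no samples in group")
  if (is.null(min_mean_ra))
    min_mean_ra <- if (domain == "bacteria") 5e-4 else 1e-5
  sub <- r$values[, samples, drop = FALSE]
  mean_ra <- rowMeans(sub)
  if (domain == "bacteria") {
    occ <- rowSums(sub > 0)
    rownames(sub)[occ >= min_occurrence & mean_ra >= min_mean_ra]
  } else {
    rownames(sub)[mean_ra >= min_mean_ra]
  }
}

#' Spearman correlation matrix with two-sided p-values
#'
#' Tie-corrected Spearman rank correlation for every unordered taxon pair
#' over the group's samples, with two-sided p from the t approximation
#' `t = rho sqrt((n-2) / (1-rho^2))` on `n - 2` df.  Taxa with constant
#' abundance across the samples have undefined correlations; their pairs
#' are recorded as missing.
#'
#' @param r a `rel_abundance_table` or numeric taxa x samples matrix.
#' @param taxa taxa to correlate (default all rows).
#' @param samples samples to use (default all columns; >= 4 required).
#' @return list with matrices `rho` and `p` (taxa x taxa; unit diagonal,
#'   `NA` for undefined pairs), `n` (samples used) and `constant_taxa`.
#' @export
spearman_matrix <- function(r, taxa = NULL, samples = NULL) {
  vals <- if (inherits(r, "rel_abundance_table")) r$values else as.matrix(r)
  if (!is.null(taxa)) vals <- vals[taxa, , drop = FALSE]
  if (!is.null(samples)) vals <- vals[, samples, drop = FALSE]
  n <- ncol(vals)
  if (n < 4L) stop("need at least 4 samples for correlation")
  const <- apply(vals, 1L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(cor(t(vals), method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  diag(rho) <- ifelse(const, NA, 1)
  r_clip <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  t_stat <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA
  list(rho = rho, p = p, n = n,
       constant_taxa = rownames(vals)[const])
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH q-values: `q_(i) = min_{j >= i} m p_(j) / j`, capped at 1 and
#' order-preserving (a thin, validated interface over
#' [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]` (`NA`s pass through).
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Build a co-occurrence network from correlation matrices
#'
#' Retains edges whose correlation passes both gates: `|rho| >= rho_min`
#' and BH-adjusted `q < q_max`.  The FDR family is the set of candidate
#' pairs of this one build: all unordered pairs for a single-domain
#' network, and only bacteria-fungus pairs for a cross-domain network
#' (within-domain pairs are never edges there, and do not enter the FDR
#' family either).  Isolated nodes are dropped.
#'
#' @param rho,p square symmetric matrices from [spearman_matrix()] (for a
#'   cross-domain network, computed on the stacked bacteria + fungi table).
#' @param domains named character vector mapping each taxon to
#'   `"bacteria"` or `"fungi"`; required for `mode = "cross_domain"`.
#' @param mode `"bacteria"`, `"fungi"` or `"cross_domain"`.
#' @param group experimental group label the network belongs to.
#' @param rho_min correlation gate (default 0.65, applied as `>=`).
#' @param q_max FDR gate (default 0.05, applied as `<`).
#' @return an object of class `co_network`: list with `graph` (an
#'   [igraph::graph] whose edges carry `rho`, `q`, `sign` and whose
#'   vertices carry `domain`), `edges` (data.frame), `group`, `mode` and
#'   the thresholds used.
#' @export
build_network <- function(rho, p, domains = NULL,
                          mode = c("bacteria", "fungi", "cross_domain"),
                          group = NA_character_,
                          rho_min = 0.65, q_max = 0.05) {
  mode <- match.arg(mode)
  if (!isTRUE(all.equal(dim(rho), dim(p))))
    stop("rho and p matrices must be aligned")
  taxa <- rownames(rho)
  if (mode == "cross_domain") {
    if (is.null(domains)) stop("cross_domain mode needs a domains vector")
    domains <- domains[taxa]
    candidate <- outer(domains, domains, "!=")
  } else {
    candidate <- matrix(TRUE, nrow(rho), ncol(rho))
    if (is.null(domains)) domains <- setNames(rep(mode, length(taxa)), taxa)
    else domains <- domains[taxa]
  }
  candidate[lower.tri(candidate, diag = TRUE)] <- FALSE
  idx <- which(candidate & !is.na(rho), arr.ind = TRUE)
  q <- rep(NA_real_, nrow(idx))
  if (nrow(idx)) q <- bh_fdr(p[idx])
  pass <- abs(rho[idx]) >= rho_min & q < q_max
  ed <- data.frame(taxon_a = taxa[idx[pass, 1L]],
                   taxon_b = taxa[idx[pass, 2L]],
                   rho = rho[idx[pass, , drop = FALSE]],
                   q = q[pass])
  ed$sign <- ifelse(ed$rho >= 0, "positive", "negative")
  g <- igraph::graph_from_data_frame(
    ed[, c("taxon_a", "taxon_b")], directed = FALSE,
    vertices = data.frame(name = taxa, domain = unname(domains)))
  igraph::E(g)$rho <- ed$rho
  igraph::E(g)$q <- ed$q
  igraph::E(g)$sign <- ed$sign
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  structure(list(graph = g, edges = ed, group = group, mode = mode,
                 rho_min = rho_min, q_max = q_max),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("co_network (%s, group %s): %d nodes, %d edges\n",
              x$mode, x$group, igraph::vcount(x$graph),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Build a network for one experimental group from count tables
#'
#' Convenience wrapper chaining [to_relative_abundance()],
#' [filter_genera()], [spearman_matrix()] and [build_network()] for a
#' single-domain or cross-domain (bacteria-fungi) network.
#'
#' @param bacteria,fungi genus-level [count_table]s (supply the one(s) the
#'   mode needs).
#' @param meta sample metadata.
#' @param group group label (`Self_open`, `Self_bagging`, `Cross_open`,
#'   `Cross_bagging`), or `"all"` for the whole dataset.
#' @inheritParams build_network
#' @inheritParams filter_genera
#' @return a `co_network`.
#' @export
group_network <- function(bacteria = NULL, fungi = NULL, meta,
                          group, mode = c("bacteria", "fungi",
                                          "cross_domain"),
                          rho_min = 0.65, q_max = 0.05,
                          min_occurrence = 5L) {
  mode <- match.arg(mode)
  grp <- assign_groups(meta)
  samples <- if (identical(group, "all")) names(grp) else
    names(grp)[grp == group]
  if (length(samples) == 0L) stop("no samples in group ", group)
  get_part <- function(ct) {
    ra <- to_relative_abundance(ct)
    keep <- filter_genera(ra, samples, domain = ct$domain,
                          min_occurrence = min_occurrence)
    list(vals = ra$values[keep, samples, drop = FALSE],
         domain = setNames(rep(ct$domain, length(keep)), keep))
  }
  parts <- list()
  if (mode %in% c("bacteria", "cross_domain")) {
    if (is.null(bacteria)) stop("mode ", mode, " needs the bacteria table")
    parts <- c(parts, list(get_part(bacteria)))
  }
  if (mode %in% c("fungi", "cross_domain")) {
    if (is.null(fungi)) stop("mode ", mode, " needs the fungi table")
    parts <- c(parts, list(get_part(fungi)))
  }
  vals <- do.call(rbind, lapply(parts, `[[`, "vals"))
  domains <- do.call(c, lapply(parts, `[[`, "domain"))
  sm <- spearman_matrix(vals)
  build_network(sm$rho, sm$p, domains = domains, mode = mode,
                group = group, rho_min = rho_min, q_max = q_max)
}

#' Detect network modules by modularity maximization
#'
#' Multilevel (Louvain) heuristic on the unweighted, sign-ignored graph,
#' deterministic under `seed`; reports the Newman-Girvan modularity Q of
#' the returned partition.
#'
#' @param net a `co_network`.
#' @param seed integer seed.
#' @return `net` with `modules` (named membership vector), `modularity`
#'   and `n_modules` filled in.
#' @export
detect_modules <- function(net, seed = 1L) {
  stopifnot(inherits(net, "co_network"))
  if (igraph::ecount(net$graph) == 0L) {
    warning("edgeless network: modularity undefined")
    net$modules <- setNames(integer(0), character(0))
    net$modularity <- NA_real_
    net$n_modules <- 0L
    return(net)
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(net$graph, weights = NA)
  net$modules <- setNames(igraph::membership(cl),
                          igraph::V(net$graph)$name)
  net$modularity <- igraph::modularity(net$graph,
                                       igraph::membership(cl))
  net$n_modules <- length(unique(net$modules))
  net
}

#' Topological summary of a co-occurrence network
#'
#' Standard descriptors on the unweighted graph: average degree `2E/N`,
#' density `2E/(N(N-1))`, mean local clustering coefficient (nodes with
#' degree < 2 contribute 0), diameter and average path length over
#' reachable (within-component) pairs, modularity of the current module
#' partition, and the percentage of positive-sign edges.
#'
#' @param net a `co_network` (run [detect_modules()] first to fill the
#'   modularity fields).
#' @return one-row data.frame of the summary statistics.
#' @export
topology <- function(net) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  data.frame(
    group = net$group, mode = net$mode,
    n_nodes = n, n_edges = e,
    avg_degree = if (n > 0) 2 * e / n else NA_real_,
    clustering_coefficient = if (n > 0)
      igraph::transitivity(g, type = "localaverage", isolates = "zero")
    else NA_real_,
    density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
    diameter = if (e > 0) igraph::diameter(g, weights = NA) else NA_real_,
    avg_path_length = if (e > 0)
      igraph::mean_distance(g, weights = NA, unconnected = TRUE)
    else NA_real_,
    modularity = if (is.null(net$modularity)) NA_real_ else net$modularity,
    n_modules = if (is.null(net$n_modules)) NA_integer_ else net$n_modules,
    pct_positive_edges = if (e > 0)
      100 * mean(igraph::E(g)$sign == "positive") else NA_real_)
}

#' Export a network edge list
#'
#' Writes `taxon_a, taxon_b, rho, q, sign, module_a, module_b` as TSV.
#'
#' @param net a `co_network`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ed <- net$edges
  mods <- net$modules
  ed$module_a <- if (is.null(mods)) NA else unname(mods[ed$taxon_a])
  ed$module_b <- if (is.null(mods)) NA else unname(mods[ed$taxon_b])
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
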