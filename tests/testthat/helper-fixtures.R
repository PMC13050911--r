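# Shared fixtures and independent oracles used across the test files.

# tiny count table: 3 taxa x 2 samples
tiny_counts <- function() {
  m <- matrix(c(2L, 2L, 4L, 5L, 0L, 3L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  count_table(m, taxonomy = c("k__Bacteria;p__A;g__G1",
                              "k__Bacteria;p__A;g__G1",
                              "k__Bacteria;p__B;g__G2"),
              domain = "bacteria")
}

random_count_table <- function(n_taxa = 8, n_samp = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samp, 20), nrow = n_taxa,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samp))))
  count_table(m, taxonomy = paste0("k__K;p__P", rep(1:2, length.out = n_taxa),
                                   ";c__C;o__O;f__F;g__G",
                                   seq_len(n_taxa)),
              domain = "bacteria")
}

# co_network built directly from an edge list (all-positive unless signed)
make_net <- function(edges, nodes = NULL, mode = "bacteria",
                     group = "test", signs = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  ed <- data.frame(taxon_a = edges[, 1], taxon_b = edges[, 2],
                   rho = 0.9, q = 0.001,
                   sign = if (is.null(signs)) "positive" else signs)
  g <- igraph::graph_from_data_frame(
    ed[, 1:2], directed = FALSE,
    vertices = data.frame(name = nodes,
                          domain = rep(mode, length(nodes))))
  igraph::E(g)$rho <- ed$rho
  igraph::E(g)$q <- ed$q
  igraph::E(g)$sign <- ed$sign
  structure(list(graph = g, edges = ed, group = group, mode = mode,
                 rho_min = 0.65, q_max = 0.05), class = "co_network")
}

# ---- oracles -------------------------------------------------------------

# all-pairs shortest-path distances by Floyd-Warshall on an adjacency matrix
oracle_dist <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# betweenness by explicit enumeration of all shortest paths (n <= 12)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_dist(adj)
  btw <- numeric(n)
  enum_paths <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (u in which(adj[s, ] > 0)) {
      if (is.finite(d[u, t]) && d[u, t] == d[s, t] - 1) {
        for (p in enum_paths(u, t)) out[[length(out) + 1L]] <- c(s, p)
      }
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t]) || d[s, t] == 0) next
    paths <- enum_paths(s, t)
    if (length(paths) == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(paths)
    }
  }
  btw
}

# top-10%-by-either-centrality core rule, recomputed from scratch
oracle_core <- function(adj, ids) {
  n <- nrow(adj)
  deg <- rowSums(adj > 0)
  btw <- round(oracle_betweenness(adj), 8L)
  k <- ceiling(0.10 * n)
  pick <- function(primary, secondary) {
    ord <- order(-primary, -secondary, ids)
    ids[ord[seq_len(k)]]
  }
  sort(union(pick(deg, btw), pick(btw, deg)))
}

# Newman-Girvan modularity of a partition, straight from the definition
oracle_modularity <- function(adj, membership) {
  m <- sum(adj[upper.tri(adj)] > 0)
  deg <- rowSums(adj > 0)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(adj[idx, idx][upper.tri(adj[idx, idx])] > 0)
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of n elements (restricted-growth strings); n <= 8
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (c in seq_len(k + 1L)) rec(c(assign, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

spearman_lattice4 <- seq(-1, 1, by = 0.2)
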