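#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth so
#' richness-sensitive indices are comparable across samples.  Samples whose
#' library is below the depth are excluded (and listed), mirroring the usual
#' practice of dropping markedly shallow samples rather than lowering the
#' depth for everyone.
#'
#' @param x a [count_table].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed; one draw per sample, recorded in the result.
#' @return a [count_table] whose columns each sum to `depth`; excluded
#'   samples and their library sizes are attached as attribute
#'   `"excluded"` (a data.frame with columns `sample_id`, `library`,
#'   `reason`), and `"rarefaction"` records depth and seed.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  stopifnot(inherits(x, "count_table"))
  if (depth < 1) stop("depth must be >= 1")
  libs <- library_sizes(x)
  if (all(libs < depth))
    stop("depth ", depth, " exceeds every library size (max ", max(libs), ")")
  drop <- libs < depth
  excluded <- data.frame(sample_id = names(libs)[drop],
                         library = unname(libs[drop]),
                         reason = sprintf("library %d < depth %d",
                                          unname(libs[drop]), depth))
  keep <- x$counts[, !drop, drop = FALSE]
  set.seed(seed)
  sub <- apply(keep, 2L, function(col) {
    if (sum(col) == depth) return(col)
    reads <- rep.int(seq_along(col), col)
    tabulate(reads[sample.int(length(reads), depth)], nbins = length(col))
  })
  dimnames(sub) <- dimnames(keep)
  out <- count_table(sub, taxonomy = x$taxonomy, domain = x$domain,
                     level = x$level)
  attr(out, "excluded") <- excluded
  attr(out, "rarefaction") <- list(depth = depth, seed = seed)
  out
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and `F2` are the
#' singleton and doubleton counts.  The bias-corrected form keeps the
#' estimator defined when a sample has no doubletons.
#'
#' @param counts non-negative integer count vector for one sample.
#' @return estimated richness (taxa); 0 for an all-zero sample.
#' @examples
#' chao1(c(5, 1, 1, 2)) # 4 + 2 * 1 / (2 * 2) = 4.5
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("chao1 requires non-negative integer counts")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i log p_i)` over taxa with nonzero proportion.
#'
#' @param counts count (or abundance) vector with positive total.
#' @return diversity in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("shannon is undefined for a zero library")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal rooted subtree spanning the tree
#' root and every taxon observed (count > 0) in the sample.  The rooted
#' convention (the path to the root is included) means a single observed
#' tip already has positive PD.
#'
#' @param counts named count vector (names are tip labels), or a logical
#'   presence vector.
#' @param tree a rooted [ape::phylo] tree with branch lengths covering all
#'   observed taxa.
#' @return PD in branch-length units; 0 when nothing is observed.
#' @export
faith_pd <- function(counts, tree) {
  if (is.null(names(counts))) stop("counts must be named by tree tip labels")
  obs <- names(counts)[counts > 0]
  if (length(obs) == 0L) return(0)
  missing <- setdiff(obs, tree$tip.label)
  if (length(missing))
    stop("observed taxon missing from tree: ", missing[1L])
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  keep <- logical(nrow(tree$edge))
  edge_of_child <- integer(max(tree$edge))
  edge_of_child[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  for (tip in match(obs, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- edge_of_child[node]
      if (keep[e]) break  # path above already collected
      keep[e] <- TRUE
      node <- parent[node]
    }
  }
  sum(tree$edge.length[keep])
}

#' Per-sample alpha-diversity table
#'
#' Optionally rarefies, then computes Chao1, Shannon and (when a tree is
#' supplied) Faith's PD for every sample.
#'
#' @param x a [count_table].
#' @param tree optional rooted [ape::phylo] over the table's taxa.
#' @param depth optional rarefaction depth; when given, [rarefy()] is
#'   applied first and excluded samples are reported.
#' @param seed rarefaction seed.
#' @return data.frame with columns `sample_id`, `chao1`, `shannon` and
#'   (if a tree is given) `pd`; attribute `"excluded"` lists any samples
#'   dropped by rarefaction.
#' @export
alpha_diversity <- function(x, tree = NULL, depth = NULL, seed = 1L) {
  excluded <- data.frame(sample_id = character(0), library = integer(0),
                         reason = character(0))
  if (!is.null(depth)) {
    x <- rarefy(x, depth, seed = seed)
    excluded <- attr(x, "excluded")
  }
  out <- data.frame(
    sample_id = sample_ids(x),
    chao1 = apply(x$counts, 2L, chao1),
    shannon = apply(x$counts, 2L, shannon),
    row.names = NULL)
  if (!is.null(tree))
    out$pd <- apply(x$counts, 2L, faith_pd, tree = tree)
  attr(out, "excluded") <- excluded
  out
}

#' Shared and unique OTUs between treatments of one species
#'
#' An OTU counts as present in a treatment when it has a nonzero count in
#' at least one of that treatment's samples for the focal species.
#'
#' @param x a [count_table].
#' @param meta sample metadata (see [read_sample_frame()]).
#' @param species focal species label (must have both treatments).
#' @return one-row data.frame: `n_shared`, `n_unique_open`,
#'   `n_unique_bagging`, `pct_unique_open`, `pct_unique_bagging` (each
#'   percentage relative to that treatment's own OTU pool).
#' @export
venn_partition <- function(x, meta, species) {
  meta <- validate_sample_frame(meta)
  if (!species %in% meta$species) stop("species not in metadata: ", species)
  pools <- lapply(c("open", "bagging"), function(tr) {
    ids <- meta$sample_id[meta$species == species & meta$treatment == tr]
    if (length(ids) == 0L)
      stop("species ", species, " has no '", tr, "' samples")
    sub <- x$counts[, intersect(ids, sample_ids(x)), drop = FALSE]
    rownames(sub)[rowSums(sub) > 0]
  })
  open <- pools[[1L]]; bag <- pools[[2L]]
  shared <- intersect(open, bag)
  u_open <- setdiff(open, bag)
  u_bag <- setdiff(bag, open)
  data.frame(species = species,
             n_shared = length(shared),
             n_unique_open = length(u_open),
             n_unique_bagging = length(u_bag),
             pct_unique_open = if (length(open)) 100 * length(u_open) /
               length(open) else NA_real_,
             pct_unique_bagging = if (length(bag)) 100 * length(u_bag) /
               length(bag) else NA_real_)
}

#' Two-way ANOVA of a diversity index on treatment and species
#'
#' Classical two-way ANOVA (`value ~ treatment * species`) for the main
#' effects of insect-exclusion treatment and host species and their
#' interaction.  With an unreplicated cell the interaction term cannot be
#' estimated and is flagged.
#'
#' @param values numeric response, one per sample.
#' @param meta data.frame with `treatment` and `species` aligned to
#'   `values`.
#' @return data.frame with one row per term: `term`, `df`, `F`, `p`;
#'   attribute `"interaction_estimable"` is `FALSE` when some cell has < 2
#'   replicates.
#' @export
two_way_anova <- function(values, meta) {
  df <- data.frame(value = values,
                   treatment = factor(meta$treatment),
                   species = factor(meta$species))
  cells <- table(df$treatment, df$species)
  estimable <- all(cells >= 2L)
  if (var(df$value) == 0) {
    terms <- c("treatment", "species", "treatment x species")
    dfs <- c(nlevels(df$treatment) - 1L, nlevels(df$species) - 1L,
             (nlevels(df$treatment) - 1L) * (nlevels(df$species) - 1L))
    out <- data.frame(term = terms, df = dfs, F = 0, p = 1)
    attr(out, "interaction_estimable") <- estimable
    return(out)
  }
  form <- if (estimable) value ~ treatment * species else
    value ~ treatment + species
  tab <- anova(aov(form, data = df))
  terms <- rownames(tab)[rownames(tab) != "Residuals"]
  out <- data.frame(term = sub(":", " x ", terms),
                    df = tab$Df[seq_along(terms)],
                    F = tab$`F value`[seq_along(terms)],
                    p = tab$`Pr(>F)`[seq_along(terms)],
                    row.names = NULL)
  if (!estimable) {
    out <- rbind(out, data.frame(term = "treatment x species", df = NA,
                                 F = NA, p = NA))
    warning("a cell has < 2 replicates; interaction not estimable")
  }
  attr(out, "interaction_estimable") <- estimable
  out
}

# Compact letter display by insert-and-absorb: start from one class holding
# all groups; every significant pair splits each class containing both;
# classes that become subsets of another are absorbed.  Letters are ordered
# by the class's highest group mean.
.compact_letters <- function(pmat, means, alpha = 0.05) {
  groups <- names(means)
  classes <- list(groups)
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  for (i in seq_len(nrow(sig))) {
    a <- rownames(pmat)[sig[i, 1L]]
    b <- colnames(pmat)[sig[i, 2L]]
    nxt <- list()
    for (cl in classes) {
      if (all(c(a, b) %in% cl)) {
        nxt <- c(nxt, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else {
        nxt <- c(nxt, list(cl))
      }
    }
    nxt <- unique(Filter(length, nxt))
    # absorb classes strictly contained in another
    keep <- vapply(seq_along(nxt), function(j)
      !any(vapply(seq_along(nxt), function(k)
        k != j && length(nxt[[j]]) < length(nxt[[k]]) &&
          all(nxt[[j]] %in% nxt[[k]]), TRUE)), TRUE)
    classes <- nxt[keep]
  }
  ord <- vapply(classes, function(cl) max(means[cl]), 0)
  classes <- classes[order(-ord)]
  letters_out <- setNames(rep("", length(means)), groups)
  for (k in seq_along(classes))
    for (g in classes[[k]])
      letters_out[g] <- paste0(letters_out[g], letters[k])
  letters_out[order(-means)]
}

#' Welch's ANOVA with Games-Howell post-hoc comparisons
#'
#' Heteroscedasticity-robust one-way comparison: Welch's F with
#' Satterthwaite denominator df, followed by Games-Howell pairwise tests
#' (studentized-range reference with Welch pairwise df) and a compact
#' letter display at `alpha`.
#'
#' @param values numeric response.
#' @param groups group labels aligned to `values` (>= 2 groups, each with
#'   >= 2 values and positive variance).
#' @param alpha significance level for the letter display.
#' @return list with `welch` (data.frame: `F`, `df1`, `df2`, `p`),
#'   `pairwise` (data.frame: `group1`, `group2`, `difference`, `p`) and
#'   `letters` (named vector, groups sharing a letter are not significantly
#'   different).
#' @export
welch_games_howell <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  vs <- tapply(values, groups, var)
  ms <- tapply(values, groups, mean)
  if (any(ns < 2L)) stop("every group needs >= 2 values")
  if (any(vs == 0))
    stop("zero-variance group '", names(vs)[vs == 0][1L],
         "'; exact ties make Welch/Games-Howell undefined — jitter or use ",
         "a rank-based test")
  w <- oneway.test(values ~ groups, var.equal = FALSE)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   difference = NA_real_, p = NA_real_)
  k <- nlevels(groups)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se2 <- vs[a] / ns[a] + vs[b] / ns[b]
    t_stat <- (ms[a] - ms[b]) / sqrt(se2)
    df_ab <- se2^2 / ((vs[a] / ns[a])^2 / (ns[a] - 1) +
                        (vs[b] / ns[b])^2 / (ns[b] - 1))
    pw$difference[i] <- ms[a] - ms[b]
    pw$p[i] <- ptukey(abs(t_stat) * sqrt(2), k, df_ab, lower.tail = FALSE)
  }
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(nrow(pw))) {
    pmat[pw$group1[i], pw$group2[i]] <- pw$p[i]
    pmat[pw$group2[i], pw$group1[i]] <- pw$p[i]
  }
  list(welch = data.frame(F = unname(w$statistic),
                          df1 = unname(w$parameter[1L]),
                          df2 = unname(w$parameter[2L]),
                          p = unname(w$p.value)),
       pairwise = pw,
       letters = .compact_letters(pmat, ms, alpha))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` between sample columns of
#' a relative-abundance table (computed with [vegan::vegdist()]).  Pairs of
#' all-zero samples are undefined and flagged.
#'
#' @param r a `rel_abundance_table` (see [to_relative_abundance()]) or a
#'   numeric taxa x samples matrix.
#' @return a `dist` object over samples; attribute `"undefined_pairs"`
#'   lists sample pairs where both columns are all-zero (entries set `NA`).
#' @export
bray_curtis <- function(r) {
  vals <- if (inherits(r, "rel_abundance_table")) r$values else as.matrix(r)
  if (ncol(vals) < 2L) stop("need at least 2 samples")
  zero <- colSums(vals) == 0
  d <- suppressWarnings(vegan::vegdist(t(vals), method = "bray"))
  und <- character(0)
  if (any(zero)) {
    m <- as.matrix(d)
    zz <- outer(zero, zero, "&")
    diag(zz) <- FALSE
    if (any(zz)) {
      idx <- which(zz & upper.tri(zz), arr.ind = TRUE)
      und <- apply(idx, 1L, function(i)
        paste(colnames(vals)[i], collapse = " vs "))
      m[zz] <- NA
      d <- stats::as.dist(m)
    }
  }
  attr(d, "undefined_pairs") <- und
  d
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Partitions the sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic by permuting
#' group labels.  `R2 = SS_among / SS_total`;
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, so p never reports 0 and
#' has resolution `1 / (n_perm + 1)`.
#'
#' @param d a `dist` object or square dissimilarity matrix.
#' @param groups group labels, one per sample (>= 2 groups, each >= 2
#'   samples).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutations.
#' @return data.frame with `R2`, `pseudo_F`, `df_among`, `df_within`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- factor(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  if (n_perm < 99L) stop("n_perm must be >= 99")
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_of <- function(g) {
    ss <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss
  }
  a <- nlevels(groups)
  f_of <- function(g) {
    ss_w <- ss_within_of(g)
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(groups)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm))
    if (f_of(groups[sample.int(n)]) >= f_obs) hits <- hits + 1L
  ss_w <- ss_within_of(groups)
  data.frame(R2 = (ss_total - ss_w) / ss_total,
             pseudo_F = f_obs,
             df_among = a - 1L, df_within = n - a,
             p = (1 + hits) / (1 + n_perm),
             n_permutations = n_perm)
}
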