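#' Identify core (keystone) genera of a network
#'
#' Nodes ranked within the top 10% (by default) for either degree or
#' betweenness centrality are defined as core taxa.  The cutoff is
#' `k = ceiling(top_frac * N)` and the two top-k sets are unioned, so a
#' genus that is central by only one criterion still qualifies.
#' Betweenness is unweighted shortest-path betweenness.  Ties at rank k are
#' broken by the other centrality, then by lexicographic id, making the
#' selection deterministic.
#'
#' @param net a `co_network`.
#' @param top_frac fraction of nodes taken from the top of each centrality
#'   ranking (default 0.10).
#' @return character vector of core genus ids (empty, with a warning, for
#'   an edgeless network); centrality scores are attached as attribute
#'   `"centrality"`.
#' @export
identify_core <- function(net, top_frac = 0.10) {
  stopifnot(inherits(net, "co_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L || igraph::ecount(g) == 0L) {
    warning("edgeless network: no core taxa")
    return(character(0))
  }
  ids <- igraph::V(g)$name
  deg <- igraph::degree(g)
  # round betweenness so mathematically tied scores are not separated by
  # floating-point accumulation order
  btw <- round(igraph::betweenness(g, weights = NA), 8L)
  k <- ceiling(top_frac * n)
  top_by <- function(primary, secondary) {
    ord <- order(-primary, -secondary, ids)
    ids[ord[seq_len(k)]]
  }
  core <- union(top_by(deg, btw), top_by(btw, deg))
  attr(core, "centrality") <- data.frame(taxon_id = ids, degree = deg,
                                         betweenness = btw,
                                         row.names = NULL)
  core
}

#' Contribution of a core genus set to the community
#'
#' For each sample of the group, the taxonomic relative abundances of all
#' core genera are summed; likewise their predicted-function relative
#' abundances (each genus's relative abundance weighted by its total
#' function weight, normalized by the community-wide function total).  The
#' mean and standard error of both per-sample sums are reported in percent.
#'
#' @param core character vector of core genus ids (may be empty).
#' @param r a `rel_abundance_table` containing every core genus.
#' @param fun optional `function_table` (see [generate_function_table()],
#'   [read_function_table()]); when `NULL` the functional contribution is
#'   `NA`.
#' @param samples sample ids of the group.
#' @return one-row data.frame: `n_core`, `taxo_mean`, `taxo_se`,
#'   `func_mean`, `func_se` (percent); per-sample sums are attached as
#'   attribute `"per_sample"`.
#' @export
core_contribution <- function(core, r, fun = NULL, samples) {
  stopifnot(inherits(r, "rel_abundance_table"))
  samples <- intersect(samples, colnames(r$values))
  if (length(samples) == 0L) stop("no samples in group")
  missing <- setdiff(core, rownames(r$values))
  if (length(missing))
    stop("core genus missing from abundance table: ", missing[1L])
  sub <- r$values[, samples, drop = FALSE]
  taxo <- if (length(core))
    colSums(sub[core, , drop = FALSE]) else setNames(rep(0, length(samples)),
                                                     samples)
  se <- function(v) if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
  func <- rep(NA_real_, length(samples))
  if (!is.null(fun)) {
    load <- tapply(fun$value, fun$taxon_id, sum)  # total function weight
    w <- setNames(rep(0, nrow(sub)), rownames(sub))
    w[names(load)[names(load) %in% names(w)]] <-
      load[names(load) %in% names(w)]
    tot <- colSums(sub * w)
    core_tot <- if (length(core))
      colSums(sub[core, , drop = FALSE] * w[core]) else rep(0, ncol(sub))
    func <- ifelse(tot > 0, 100 * core_tot / tot, NA_real_)
  }
  out <- data.frame(n_core = length(core),
                    taxo_mean = mean(100 * taxo),
                    taxo_se = se(100 * taxo),
                    func_mean = mean(func),
                    func_se = if (all(is.na(func))) NA_real_ else se(func))
  attr(out, "per_sample") <- data.frame(sample_id = samples,
                                        taxo_pct = 100 * unname(taxo),
                                        func_pct = unname(func))
  out
}

#' Summarize core-genus counts across groups and domains
#'
#' Totals a per-group, per-domain core-genus count table (as produced from
#' the cross-domain networks of each experimental group) into overall and
#' per-domain counts and each group's percentage share of the total.
#'
#' @param counts data.frame with columns `domain`, `group`, `n_core`.
#' @return list with `total`, `by_domain` (named vector) and `group_share`
#'   (named vector of percentages of the total, combining domains).
#' @export
core_count_summary <- function(counts) {
  stopifnot(all(c("domain", "group", "n_core") %in% names(counts)))
  total <- sum(counts$n_core)
  by_domain <- tapply(counts$n_core, counts$domain, sum)
  by_group <- tapply(counts$n_core, counts$group, sum)
  list(total = total,
       by_domain = setNames(as.numeric(by_domain), names(by_domain)),
       group_share = setNames(100 * as.numeric(by_group) / total,
                              names(by_group)))
}

#' Pollen remaining rate per open-treatment replicate
#'
#' `rate_i = 100 * open_i / mean(bagging)` for one species: each open
#' replicate's grain count relative to the species' mean bagged (insect
#' -excluded) grain count.  Rates above 100% are legitimate (an open flower
#' can hold more pollen than the bagged average).
#'
#' @param pollen data.frame with columns `species`, `treatment`,
#'   `replicate`, `grains` (see [generate_pollen_counts()]).
#' @param species focal species label.
#' @return data.frame with columns `species`, `replicate`, `rate` (percent).
#' @export
remaining_rate <- function(pollen, species) {
  sub <- pollen[pollen$species == species, , drop = FALSE]
  bag <- sub$grains[sub$treatment == "bagging"]
  opn <- sub[sub$treatment == "open", , drop = FALSE]
  if (length(bag) == 0L) stop("no bagging replicates for ", species)
  if (mean(bag) <= 0) stop("bagging mean is zero for ", species)
  data.frame(species = species, replicate = opn$replicate,
             rate = 100 * opn$grains / mean(bag))
}

#' One-way ANOVA with Tukey HSD comparisons of remaining rates
#'
#' Tests homogeneity of variances first (Levene's test via
#' [car::leveneTest()]), then fits a one-way ANOVA across species and runs
#' Tukey HSD pairwise comparisons with a compact letter display at `alpha`.
#'
#' @param rates numeric response (e.g. remaining rates, percent).
#' @param species group labels aligned to `rates` (>= 2 species, each with
#'   >= 2 replicates).
#' @param alpha significance level for the letter display.
#' @return list with `levene` (data.frame: `F`, `df1`, `df2`, `p`),
#'   `anova` (data.frame: `F`, `df1`, `df2`, `p`), `tukey` (data.frame:
#'   `group1`, `group2`, `difference`, `p`) and `letters`.
#' @export
tukey_anova <- function(rates, species, alpha = 0.05) {
  species <- factor(species)
  if (nlevels(species) < 2L) stop("need at least 2 species")
  if (any(table(species) < 2L)) stop("every species needs >= 2 replicates")
  lev <- car::leveneTest(rates ~ species)
  fit <- aov(rates ~ species)
  tab <- anova(fit)
  tk <- TukeyHSD(fit)$species
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- data.frame(group1 = vapply(pairs, `[`, "", 1L),
                      group2 = vapply(pairs, `[`, "", 2L),
                      difference = tk[, "diff"], p = tk[, "p adj"],
                      row.names = NULL)
  ms <- tapply(rates, species, mean)
  k <- nlevels(species)
  pmat <- matrix(NA_real_, k, k, dimnames = list(levels(species),
                                                 levels(species)))
  for (i in seq_len(nrow(tukey))) {
    pmat[tukey$group1[i], tukey$group2[i]] <- tukey$p[i]
    pmat[tukey$group2[i], tukey$group1[i]] <- tukey$p[i]
  }
  list(levene = data.frame(F = lev[1L, "F value"], df1 = lev[1L, "Df"],
                           df2 = lev[2L, "Df"], p = lev[1L, "Pr(>F)"]),
       anova = data.frame(F = tab$`F value`[1L], df1 = tab$Df[1L],
                          df2 = tab$Df[2L], p = tab$`Pr(>F)`[1L]),
       tukey = tukey,
       letters = .compact_letters(pmat, ms, alpha))
}

#' Bootstrap species-level Spearman correlation
#'
#' For two variables measured on unpaired replicates within each species:
#' per iteration, each species' replicates of x and of y are resampled
#' independently with replacement, species means are taken, and Spearman's
#' rho is computed across species means.  The distribution of rho over
#' iterations gives its median, mean and percentile 95% CI.  Iterations
#' where rho is undefined (zero variance of the resampled species means)
#' are recorded as missing.
#'
#' @param x,y named lists of replicate vectors, one element per species
#'   (same species names; >= 3 species, >= 2 replicates each).
#' @param n_iter bootstrap iterations (default 5000).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return list with `rho` (vector of drawn values, `NA` for undefined
#'   iterations), `median`, `mean`, `ci` (percentile interval; endpoints
#'   are members of the empirical distribution), `n_iterations`,
#'   `n_missing` and `n_species`.
#' @export
bootstrap_species_spearman <- function(x, y, n_iter = 5000L, seed = 1L,
                                       conf = 0.95) {
  sp <- names(x)
  if (is.null(sp) || !identical(sort(sp), sort(names(y))))
    stop("x and y must be named lists over the same species")
  if (length(sp) < 3L) stop("need at least 3 species")
  if (any(lengths(x) < 2L) || any(lengths(y) < 2L))
    stop("every species needs >= 2 replicates per variable")
  y <- y[sp]
  set.seed(seed)
  rho <- vapply(seq_len(n_iter), function(i) {
    mx <- vapply(x, function(v) mean(sample(v, replace = TRUE)), 0)
    my <- vapply(y, function(v) mean(sample(v, replace = TRUE)), 0)
    if (sd(mx) == 0 || sd(my) == 0) return(NA_real_)
    cor(mx, my, method = "spearman")
  }, 0)
  ok <- rho[!is.na(rho)]
  a <- (1 - conf) / 2
  ci <- quantile(ok, c(a, 1 - a), type = 1, names = FALSE)
  list(rho = rho, median = median(ok), mean = mean(ok), ci = ci,
       n_iterations = n_iter, n_missing = sum(is.na(rho)),
       n_species = length(sp))
}

#' Cohen's d from group means and dispersions
#'
#' Pooled-SD standardized mean difference `(m1 - m2) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.  Dispersions
#' may be given as standard deviations or standard errors (SEs are
#' converted via `s = se * sqrt(n)`), so the statistic can be recomputed
#' directly from reported summary tables.
#'
#' @param m1,m2 group means.
#' @param disp1,disp2 group dispersions (> 0), interpreted per
#'   `dispersion_kind`.
#' @param n1,n2 group sizes (>= 2).
#' @param dispersion_kind `"sd"` or `"se"`.
#' @return Cohen's d (unitless, signed as `m1 - m2`).
#' @examples
#' cohens_d(83.01, 2.87, 5, 97.23, 0.59, 5, "se") # about -3.07
#' @export
cohens_d <- function(m1, disp1, n1, m2, disp2, n2,
                     dispersion_kind = c("sd", "se")) {
  dispersion_kind <- match.arg(dispersion_kind)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group")
  if (disp1 <= 0 || disp2 <= 0) stop("dispersions must be positive")
  s1 <- if (dispersion_kind == "se") disp1 * sqrt(n1) else disp1
  s2 <- if (dispersion_kind == "se") disp2 * sqrt(n2) else disp2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled variance is zero")
  (m1 - m2) / sp
}
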