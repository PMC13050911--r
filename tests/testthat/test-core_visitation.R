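test_that("keystone rule: star hub is the sole core node", {
  star <- make_net(cbind("hub", paste0("leaf", 1:9)))
  core <- identify_core(star)
  expect_identical(as.character(core), "hub")
})

test_that("a node in the top decile of betweenness only is still core", {
  # two hubs of triangle-rich lobes joined through a low-degree bridge:
  # the bridge node carries all inter-lobe shortest paths
  lobe <- function(tag) t(combn(paste0(tag, 1:7), 2))
  edges <- rbind(lobe("L"), lobe("R"), c("L1", "bridge"), c("bridge", "R1"))
  net <- make_net(edges)
  core <- identify_core(net)
  deg <- igraph::degree(net$graph)
  expect_lt(deg["bridge"], sort(deg, decreasing = TRUE)[2])
  expect_true("bridge" %in% core)
})

test_that("core identification equals the exhaustive oracle on small graphs", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:200) {
    n <- sample(4:12, 1)
    adj <- matrix(0, n, n)
    up <- which(upper.tri(adj))
    adj[up[runif(length(up)) < 0.35]] <- 1
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    ids <- sprintf("v%02d", seq_len(n))
    dimnames(adj) <- list(ids, ids)
    keep <- rowSums(adj) > 0
    adj <- adj[keep, keep, drop = FALSE]
    ids <- ids[keep]
    el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    net <- make_net(cbind(ids[el[, 1]], ids[el[, 2]]), nodes = ids)
    expect_identical(sort(as.character(identify_core(net))),
                     oracle_core(adj, ids))
    expect_lte(length(identify_core(net)), 2 * ceiling(0.1 * length(ids)))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 190)
})

test_that("edgeless networks yield an empty core set with a warning", {
  net <- make_net(rbind(c("a", "b")))
  net$graph <- igraph::delete_edges(net$graph, 1)
  expect_warning(core <- identify_core(net), "no core taxa")
  expect_length(core, 0)
})

test_that("core contribution sums per-sample shares with mean and SE", {
  m <- matrix(c(10L, 30L, 60L, 20L, 30L, 50L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ra <- to_relative_abundance(count_table(m, domain = "fungi"))
  # complete core -> exactly 100%, SE 0
  all_core <- core_contribution(c("g1", "g2", "g3"), ra,
                                samples = c("s1", "s2"))
  expect_equal(all_core$taxo_mean, 100)
  expect_equal(all_core$taxo_se, 0)
  # empty core -> 0%
  expect_equal(core_contribution(character(0), ra,
                                 samples = c("s1", "s2"))$taxo_mean, 0)
  # guild-style function table (weight 1 per genus): functional == taxonomic
  fun <- generate_function_table(c("g1", "g2", "g3"), "fungi", seed = 1)
  cc <- core_contribution(c("g1", "g3"), ra, fun, c("s1", "s2"))
  expect_equal(cc$func_mean, cc$taxo_mean)
  expect_equal(cc$func_se, cc$taxo_se)
  # hand value: shares 0.7 and 0.7
  expect_equal(cc$taxo_mean, 70)
  expect_error(core_contribution("nope", ra, samples = "s1"),
               "missing from abundance table")
  # additivity over disjoint core sets, per sample
  a <- attr(core_contribution("g1", ra, samples = c("s1", "s2")),
            "per_sample")$taxo_pct
  b <- attr(core_contribution(c("g2", "g3"), ra, samples = c("s1", "s2")),
            "per_sample")$taxo_pct
  expect_equal(a + b, rep(100, 2))
})

test_that("planted core abundance is recovered on synthetic data", {
  # the planted share is a ~95% coverage statement per dataset, so check
  # the within-2-SE property across several independent datasets
  hits <- vapply(11:20, function(s) {
    dat <- generate_counts(synth_spec(seed = s))
    grp <- assign_groups(dat$meta)
    smp <- names(grp)[grp == "Cross_open"]
    ra <- to_relative_abundance(dat$fungi)
    cc <- core_contribution(dat$truth$fungi$core, ra, samples = smp)
    abs(cc$taxo_mean - 85) <= 2 * cc$taxo_se
  }, TRUE)
  expect_gte(mean(hits), 0.7)
})

test_that("remaining rate is open counts over the bagged mean", {
  pollen <- data.frame(
    species = "CA",
    treatment = rep(c("open", "bagging"), c(3, 2)),
    replicate = c(1:3, 1:2),
    grains = c(80, 50, 90, 70, 90))  # bagging mean 80
  rr <- remaining_rate(pollen, "CA")
  expect_equal(rr$rate, c(100, 62.5, 112.5))  # >100% allowed
  pollen$grains[4:5] <- 0
  expect_error(remaining_rate(pollen, "CA"), "bagging mean is zero")
})

test_that("Tukey ANOVA reduces to the pooled t-test at two groups", {
  set.seed(12)
  x <- c(rnorm(6, 0), rnorm(6, 1))
  g <- rep(c("a", "b"), each = 6)
  res <- tukey_anova(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(res$tukey$p, tt$p.value, tolerance = 1e-8)
  expect_true(all(c("levene", "anova") %in% names(res)))

  # identical groups -> F = 0 and a single shared letter
  res0 <- tukey_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$anova$F, 0)
  expect_equal(unname(res0$letters), c("a", "a"))
})

test_that("field-like remaining rates reproduce the robust letter contrasts", {
  # CA (lowest) always earns its own letter and MC always separates from
  # LA; the SM-LA contrast is genuinely borderline at the field SEs
  # (Tukey q sits almost on the critical value), so it is not asserted
  shares <- function(a, b)
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  res <- vapply(1:20, function(s) {
    pollen <- generate_pollen_counts(synth_spec(seed = s))
    rates <- do.call(rbind, lapply(c("CA", "SM", "LA", "MC"), function(sp)
      remaining_rate(pollen, sp)))
    L <- tukey_anova(rates$rate, rates$species)$letters
    c(ca_distinct = !shares(L[["CA"]], paste0(L[["SM"]], L[["LA"]],
                                              L[["MC"]])),
      mc_above_la = !shares(L[["MC"]], L[["LA"]]) &&
        which(names(L) == "MC") == 1L)
  }, c(TRUE, TRUE))
  expect_gte(mean(res["ca_distinct", ]), 0.95)
  expect_gte(mean(res["mc_above_la", ]), 0.95)
})

test_that("bootstrap species-level Spearman has the exact n=4 support", {
  set.seed(30)
  x <- lapply(setNames(c(64, 90, 83, 97), c("CA", "SM", "LA", "MC")),
              function(m) rnorm(5, m, 3))
  y <- lapply(setNames(c(10, 30, 25, 40), c("CA", "SM", "LA", "MC")),
              function(m) rnorm(5, m, 6))
  bs <- bootstrap_species_spearman(x, y, n_iter = 1500, seed = 2)
  drawn <- bs$rho[!is.na(bs$rho)]
  expect_true(all(vapply(drawn, function(r)
    any(abs(r - spearman_lattice4) < 1e-9), TRUE)))
  expect_true(bs$ci[1] <= bs$median && bs$median <= bs$ci[2])
  expect_true(all(bs$ci %in% drawn))  # percentile endpoints are draws
  # deterministic under seed
  bs2 <- bootstrap_species_spearman(x, y, n_iter = 1500, seed = 2)
  expect_identical(bs$rho, bs2$rho)

  # degenerate: zero within-species variance, monotone means -> rho = 1
  x0 <- lapply(c(a = 1, b = 2, c = 3, d = 4), function(m) rep(m, 3))
  y0 <- lapply(c(a = 5, b = 6, c = 7, d = 8), function(m) rep(m, 3))
  b0 <- bootstrap_species_spearman(x0, y0, n_iter = 50, seed = 1)
  expect_true(all(b0$rho == 1))
  expect_equal(unname(b0$ci), c(1, 1))

  expect_error(bootstrap_species_spearman(x[1:2], y[1:2]),
               "at least 3 species")
})

test_that("bootstrap CI separates planted effects from the null", {
  # strong positive species-level association: CI excludes 0
  set.seed(5)
  means <- c(a = 10, b = 20, c = 30, d = 40, e = 50, f = 60)
  x <- lapply(means, function(m) rnorm(5, m, 1))
  y <- lapply(means, function(m) rnorm(5, 2 * m, 2))
  bs <- bootstrap_species_spearman(x, y, n_iter = 1000, seed = 9)
  expect_gt(bs$ci[1], 0)
  # null: CI covers 0 in most simulations
  cover <- vapply(1:40, function(s) {
    set.seed(s + 1000)
    xn <- lapply(means, function(m) rnorm(4, 0, 1))
    yn <- lapply(means, function(m) rnorm(4, 0, 1))
    b <- bootstrap_species_spearman(xn, yn, n_iter = 300, seed = s)
    b$ci[1] <= 0 && b$ci[2] >= 0
  }, TRUE)
  expect_gte(mean(cover), 0.85)
})

test_that("Cohen's d handles SE inputs and is antisymmetric", {
  expect_equal(cohens_d(5, 1, 5, 5, 1, 5, "sd"), 0)
  d <- cohens_d(83.01, 2.87, 5, 97.23, 0.59, 5, "se")
  expect_equal(d, -3.07, tolerance = 5e-3)
  expect_equal(cohens_d(97.23, 0.59, 5, 83.01, 2.87, 5, "se"), -d)
  # se path equals sd path after conversion (algebraic identity)
  expect_equal(cohens_d(10, 2, 8, 12, 3, 6, "se"),
               cohens_d(10, 2 * sqrt(8), 8, 12, 3 * sqrt(6), 6, "sd"))
  expect_error(cohens_d(1, 0.5, 1, 2, 0.5, 5), "n >= 2")
})

test_that("core-count summaries total the per-group table", {
  counts <- utils::read.delim(system.file("extdata",
                                          "worked_example_core_counts.tsv",
                                          package = "pollenet"))
  s <- core_count_summary(counts)
  expect_equal(s$total, 90)
  expect_equal(unname(s$by_domain[c("bacteria", "fungi")]), c(51, 39))
  expect_equal(unname(s$group_share[["Cross_open"]]), 100 * 80 / 90,
               tolerance = 1e-9)
})
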