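test_that("rarefaction subsamples to exact depth and excludes shallow samples", {
  m <- matrix(c(5L, 4L, 1L, 3L, 2L, 1L, 30L, 20L, 10L), nrow = 3,
              dimnames = list(paste0("t", 1:3), paste0("s", 1:3)))
  ct <- count_table(m, domain = "bacteria")
  r <- rarefy(ct, 10, seed = 1)
  expect_equal(unname(colSums(r$counts)), rep(10L, 2))
  expect_equal(attr(r, "excluded")$sample_id, "s2")  # library 6 < 10
  # a sample already at depth is unchanged
  expect_equal(unname(r$counts[, "s1"]), c(5L, 4L, 1L))
  expect_error(rarefy(ct, 1000), "exceeds every library")

  # hypergeometric expectation: mean rarefied counts of [10,0,10] at half
  # depth approach [5,0,5]
  m2 <- matrix(c(10L, 0L, 10L), ncol = 1, dimnames = list(paste0("t", 1:3),
                                                          "s1"))
  ct2 <- count_table(m2, domain = "bacteria")
  draws <- sapply(1:400, function(s) rarefy(ct2, 10, seed = s)$counts[, 1])
  expect_equal(unname(rowMeans(draws)), c(5, 0, 5), tolerance = 0.1)
  # rarefaction never increases observed richness
  expect_true(all(colSums(r$counts > 0) <=
                    colSums(ct$counts[, colnames(r$counts)] > 0)))
})

test_that("chao1 matches the bias-corrected formula and vegan", {
  expect_equal(chao1(c(5, 3, 2)), 3)            # no singletons -> S_obs
  expect_equal(chao1(c(5, 1, 1, 2)), 4.5)       # 4 + 2*1/(2*2)
  expect_equal(chao1(c(0, 0, 0)), 0)
  expect_error(chao1(c(1.5, 2)), "integer")
  for (seed in 1:10) {
    set.seed(seed)
    x <- rpois(50, 1.2)
    expect_equal(chao1(x), unname(vegan::estimateR(x)["S.chao1"]))
    expect_gte(chao1(x), sum(x > 0))  # never below observed richness
  }
})

test_that("shannon uses natural log and is maximal for even composition", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)))
  expect_error(shannon(c(0, 0)), "zero library")
  set.seed(1)
  for (i in 1:10) {
    x <- rpois(6, 10) + 1
    expect_lte(shannon(x), shannon(rep(1, 6)) + 1e-12)
  }
})

test_that("faith_pd follows the rooted-subtree convention", {
  star <- generate_tree(paste0("t", 1:5), type = "star")
  expect_equal(faith_pd(setNames(c(1, 1, 1, 0, 0), star$tip.label), star), 3)
  # all tips observed -> total branch length
  tr <- generate_tree(paste0("t", 1:9), seed = 4)
  all_obs <- setNames(rep(1, 9), tr$tip.label)
  expect_equal(faith_pd(all_obs, tr), sum(tr$edge.length))
  expect_error(faith_pd(c(zz = 1), tr), "missing from tree: zz")

  # monotone non-decreasing as taxa are added; agrees with picante
  skip_if_not_installed("picante")
  for (seed in 1:25) {
    tr <- generate_tree(paste0("t", 1:8), seed = seed)
    pres <- setNames(rep(0, 8), tr$tip.label)
    last <- 0
    ord <- sample(tr$tip.label)
    for (tip in ord) {
      pres[tip] <- 1
      pd <- faith_pd(pres, tr)
      expect_gte(pd, last)
      last <- pd
    }
    ref <- picante::pd(matrix(pres, nrow = 1,
                              dimnames = list("s", names(pres))),
                       tr, include.root = TRUE)$PD
    expect_equal(pd, ref)
  }
})

test_that("venn partition counts shared and unique OTUs per treatment", {
  m <- matrix(c(1L, 1L, 0L,   # open sample: A, B
                0L, 1L, 1L),  # bagging sample: B, C
              nrow = 3, dimnames = list(c("A", "B", "C"), c("o1", "b1")))
  ct <- count_table(m, domain = "bacteria")
  meta <- data.frame(sample_id = c("o1", "b1"), species = "CA",
                     treatment = c("open", "bagging"),
                     pollination = "self", replicate = c(1L, 1L))
  v <- venn_partition(ct, meta, "CA")
  expect_equal(v$n_shared, 1L)
  expect_equal(v$n_unique_open, 1L)
  expect_equal(v$n_unique_bagging, 1L)
  expect_equal(v$pct_unique_open, 50)

  # identical pools -> nothing unique; disjoint pools -> all unique
  m[] <- 1L
  expect_equal(venn_partition(count_table(m, domain = "bacteria"),
                              meta, "CA")$pct_unique_open, 0)
  m[, 1] <- c(1L, 0L, 0L); m[, 2] <- c(0L, 1L, 1L)
  v3 <- venn_partition(count_table(m, domain = "bacteria"), meta, "CA")
  expect_equal(v3$pct_unique_open, 100)
  expect_equal(v3$pct_unique_bagging, 100)
  expect_error(venn_partition(ct, meta, "ZZ"), "species not in metadata")
})

test_that("two-way ANOVA recovers hand-computed and structural answers", {
  meta <- expand.grid(replicate = 1:2, treatment = c("open", "bagging"),
                      species = c("A", "B"), stringsAsFactors = FALSE)
  # hand-computed 2x2 with 2 replicates per cell
  vals <- c(10, 12, 20, 22, 30, 32, 44, 46)
  res <- two_way_anova(vals, meta)
  fit <- anova(aov(vals ~ treatment * species,
                   data = transform(meta, treatment = factor(treatment),
                                    species = factor(species))))
  expect_equal(res$F, fit$`F value`[1:3])
  # grand-mean only -> F = 0 (all p = 1 for constant response)
  res0 <- two_way_anova(rep(5, 8), meta)
  expect_true(all(res0$F == 0))
  expect_true(all(res0$p == 1))

  # additive species shift, no interaction
  set.seed(7)
  meta2 <- expand.grid(replicate = 1:10, treatment = c("open", "bagging"),
                       species = c("A", "B"), stringsAsFactors = FALSE)
  v2 <- rnorm(40, sd = 0.5) + ifelse(meta2$species == "B", 10, 0)
  r2 <- two_way_anova(v2, meta2)
  expect_gt(r2$F[r2$term == "species"], 100)
  expect_lt(r2$F[r2$term == "treatment x species"], 5)

  meta$replicate[1] <- 99  # still 2 per cell; now break a cell
  expect_warning(two_way_anova(vals[-1], meta[-1, ]), "interaction")
})

test_that("Welch ANOVA and Games-Howell reduce to the Welch t-test at k = 2", {
  set.seed(3)
  x <- c(rnorm(8, 0, 1), rnorm(12, 1, 3))
  g <- rep(c("a", "b"), c(8, 12))
  res <- welch_games_howell(x, g)
  tt <- t.test(x ~ g, var.equal = FALSE)
  expect_equal(res$welch$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$pairwise$p, tt$p.value, tolerance = 1e-8)

  # identical groups -> F = 0
  res0 <- welch_games_howell(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$welch$F, 0)

  # a group shifted by 10 SDs earns its own letter
  set.seed(4)
  y <- c(rnorm(6), rnorm(6), rnorm(6) + 10)
  gg <- rep(c("a", "b", "c"), each = 6)
  res3 <- welch_games_howell(y, gg)
  expect_false(res3$letters["c"] %in% res3$letters[c("a", "b")])

  expect_error(welch_games_howell(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero-variance")
})

test_that("Bray-Curtis matches hand values and metric properties", {
  x <- cbind(s1 = c(.5, .5, 0), s2 = c(0, .5, .5), s3 = c(.5, .5, 0))
  rownames(x) <- paste0("t", 1:3)
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # disjoint supports -> 1
  y <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.matrix(bray_curtis(y))["a", "b"], 1)
  # all values in [0, 1] on random compositions
  set.seed(2)
  z <- matrix(runif(60), nrow = 6); z <- sweep(z, 2, colSums(z), "/")
  colnames(z) <- paste0("s", 1:10)
  expect_true(all(bray_curtis(z) >= 0 & bray_curtis(z) <= 1))
  # double-zero pair flagged
  w <- cbind(a = c(1, 1), b = c(0, 0), c = c(0, 0))
  dd <- bray_curtis(w)
  expect_match(attr(dd, "undefined_pairs"), "b vs c")
})

test_that("PERMANOVA agrees with vegan::adonis2 and behaves at the limits", {
  set.seed(10)
  m <- matrix(runif(30 * 12), nrow = 30)
  m <- sweep(m, 2, colSums(m), "/")
  colnames(m) <- paste0("s", 1:12); rownames(m) <- paste0("t", 1:30)
  d <- bray_curtis(m)
  g <- rep(c("A", "B", "C"), each = 4)
  mine <- permanova(d, g, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(d ~ g, permutations = 199)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_gt(mine$p, 0)  # p never reports 0; resolution 1/(n_perm+1)
  expect_equal(mine$p %% (1 / 200), 0, tolerance = 1e-12)

  # identical duplicated samples per group, distinct between groups: R2 -> 1
  a <- c(1, 0, 0); b <- c(0, 0, 1)
  md <- cbind(s1 = a, s2 = a, s3 = a, s4 = b, s5 = b, s6 = b)
  rownames(md) <- paste0("t", 1:3)
  r1 <- permanova(bray_curtis(md), rep(c("x", "y"), each = 3),
                  n_perm = 99, seed = 1)
  expect_equal(r1$R2, 1)

  # R2 invariant to label renaming
  g2 <- c(A = "Q", B = "W", C = "Z")[g]
  expect_equal(permanova(d, g2, n_perm = 99, seed = 1)$R2, mine$R2)

  expect_error(permanova(d, rep("A", 12), n_perm = 99), "at least 2 groups")
})
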