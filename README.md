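# pollenet

Analysis pipeline for pollen microbiome studies under factorial
pollination-exclusion designs: which microbes live in pollen, how insect
visitation and host identity reshape them, and which taxa hold the
community together.

## The problem

In a typical design, several crop species — some self-pollinated, some
insect-dependent cross-pollinated — are sampled under an **open** treatment
(flowers freely visited) and a **bagging** treatment (mesh bags excluding
insects), with replicate pollen pools per species × treatment.  Amplicon
sequencing yields bacterial (16S) and fungal (ITS) count tables.  The
questions: do visitation and host identity shift community structure and
diversity; how do co-occurrence patterns change; and which *core* taxa
dominate, especially in cross-pollinated open flowers?

`pollenet` takes finished taxa × sample count tables (plus metadata, an
optional phylogeny and predicted-function tables) and provides:

* **Alpha diversity**: rarefaction (without replacement, shallow samples
  excluded and listed), bias-corrected Chao1
  `S_obs + F1(F1−1)/(2(F2+1))`, Shannon `H = −Σ p_i ln p_i`, rooted
  Faith's PD; two-way ANOVA (treatment × species) and Welch ANOVA with
  Games–Howell post-hoc letters.
* **Beta diversity**: Bray–Curtis `Σ|x−y| / Σ(x+y)` on non-rarefied
  relative abundances; one-way PERMANOVA with
  `R² = SS_among/SS_total`, `p = (1 + #{F* ≥ F})/(1 + n_perm)`.
* **Co-occurrence networks**: per-group genus filtering (bacteria:
  ≥ 5-sample occurrence and mean RA ≥ 0.05%; fungi: mean RA ≥ 0.001%),
  Spearman correlation with edges gated by `|ρ| ≥ 0.65` **and** BH
  `q < 0.05`; cross-domain (bacteria–fungi) networks restricted to
  between-domain pairs; Louvain modules with Newman–Girvan Q; topology
  summaries.
* **Core (keystone) taxa**: union of the top 10% of nodes by degree or by
  betweenness centrality (`k = ⌈0.1·N⌉`, deterministic tie-breaks), and
  their taxonomic / predicted-functional contribution (mean ± SE of
  per-sample summed relative abundance).
* **Visitation statistics**: pollen remaining rate
  `100·open/mean(bagging)`, one-way ANOVA + Tukey HSD letters, bootstrap
  species-level Spearman ρ with percentile 95% CI, and Cohen's
  `d = (m₁−m₂)/s_pooled` computable straight from `mean ± SE` tables.
* **Synthetic data**: a study-shaped generator (latent Gaussian copula +
  multinomial reads) with planted correlation blocks, a planted core set
  and calibrated pollen counts, so every estimator is testable against
  known ground truth.

## Worked example

```r
library(pollenet)

dat <- generate_counts(synth_spec(seed = 42))   # 40 samples, 2 domains
dat$bacteria
#> count_table: 150 genus-level taxa x 40 samples (bacteria)
#>   total reads: 2636987; library sizes 39079-89251

net <- group_network(dat$bacteria, dat$fungi, dat$meta,
                     group = "all", mode = "bacteria")
net <- detect_modules(net, seed = 42)
topology(net)[, c("n_nodes", "n_edges", "avg_degree", "modularity")]
#>   n_nodes n_edges avg_degree modularity
#> 1      16      22       2.75  0.5661157

identify_core(net)                               # top decile by degree or
#> [1] "gB018" "gB021" "gB014" "gB015"            # betweenness centrality

grp <- assign_groups(dat$meta)
cc <- core_contribution(dat$truth$fungi$core,
                        to_relative_abundance(dat$fungi),
                        samples = names(grp)[grp == "Cross_open"])
round(cc[, c("n_core", "taxo_mean", "taxo_se")], 2)
#>   n_core taxo_mean taxo_se
#> 1     12     81.08     2.5
```

The 16-node network contains the three planted 6-genus correlation blocks
(45 planted pairs; 22 pass the per-group gates here), its core set is the
blocks' hub genera, and the planted fungal core (true share 85%) is
recovered at 81.1 ± 2.5% in this dataset's Cross_open samples.

Remaining rates from the calibrated pollen generator:

```r
pollen <- generate_pollen_counts(synth_spec(seed = 42))
rates <- do.call(rbind, lapply(c("CA", "SM", "LA", "MC"),
                               function(sp) remaining_rate(pollen, sp)))
tukey_anova(rates$rate, rates$species)$letters
#>   MC   SM   LA   CA
#>  "a" "ab"  "b"  "c"
cohens_d(83.01, 2.87, 5, 97.23, 0.59, 5, "se")   # LA vs MC, from mean±SE
#> [1] -3.069442
```

Lower remaining rate means more pollen removed, i.e. more insect
visitation; CA loses the most pollen and MC the least, and the LA–MC
standardized difference is a very large effect (d ≈ −3.07).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/pollenet.R simulate --seed 1 --out data/
Rscript inst/cli/pollenet.R network --bacteria data/bacteria_genus.tsv \
    --fungi data/fungi_genus.tsv --meta data/metadata.tsv \
    --group Cross_open --mode cross_domain --out net/
Rscript inst/cli/pollenet.R run-all --seed 1 --out run/
```

## Package layout

* `R/count_table.R` — data model, TSV IO, relative abundance, taxonomic
  aggregation, group assignment
* `R/synthetic.R` — the synthetic-data generators
* `R/diversity.R` — rarefaction, alpha indices, ANOVA tools, Bray–Curtis,
  PERMANOVA
* `R/network.R` — filtering, Spearman/FDR gating, network assembly,
  modules, topology
* `R/core.R` — keystone identification, contributions, visitation
  statistics
* `R/pipeline.R` — configuration and end-to-end orchestration with a
  provenance manifest
* `vignettes/pollen-microbiome-methods.Rmd` — full methods description
  and design rationale
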