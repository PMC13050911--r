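---
title: "Methods: pollen microbiome diversity, networks and core taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pollen microbiome diversity, networks and core taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenet)
```

## The scientific setting

Pollen carries a resident microbial community, and flower-visiting insects
are both pollinators and microbial vectors.  A standard way to isolate the
insects' contribution is a factorial field design: several host species —
some predominantly self-pollinated, some insect-dependent cross-pollinated
— each sampled under an *open* treatment (flowers freely visited) and a
*bagging* treatment (buds enclosed in fine mesh that excludes visitors),
with a fixed number of replicate pollen pools per species × treatment.
`pollenet` implements the complete downstream analysis for such a design,
taking finished genus/OTU count tables (amplicon read counts after
clustering and taxonomic annotation, which are out of scope here) and
producing:

1. **Alpha diversity** — rarefaction, bias-corrected Chao1, Shannon
   (natural log), Faith's PD — with two-way ANOVA over treatment × species
   and heteroscedasticity-robust post-hoc comparisons.
2. **Beta diversity** — Bray–Curtis dissimilarity on relative abundances
   from the *non-rarefied* tables, tested by one-way PERMANOVA on the
   composite pollination-type × treatment group.
3. **Co-occurrence networks** — Spearman correlations between genera,
   gated by an effect-size threshold and a Benjamini–Hochberg FDR
   threshold; single-domain (bacteria, fungi) and cross-domain
   (bacteria–fungi) variants; modularity-based module detection; topology
   summaries.
4. **Core (keystone) taxa** — nodes in the top decile of degree *or*
   betweenness centrality — and their taxonomic and predicted-functional
   contribution to the community.
5. **Insect-visitation statistics** — the pollen remaining rate, its
   one-way ANOVA with Tukey HSD letters, a bootstrap species-level
   Spearman correlation, and Cohen's *d*.

A synthetic-data generator with *planted* structure (known correlation
blocks, a known high-abundance core set, calibrated pollen counts) gives
every stage a ground truth to be validated against.

## Sample groups

Samples are classified by the host's pollination system crossed with the
exclusion treatment into `Self_open`, `Self_bagging`, `Cross_open` and
`Cross_bagging`.  Networks and core-taxon reports are computed per group;
PERMANOVA uses the composite group as its single factor, which is why one
R² per domain is reported rather than separate treatment and species
terms.

## Alpha diversity: conventions that matter

Several small conventions are pinned so that results are exactly
reproducible:

* **Chao1** uses the bias-corrected form
  `S_obs + F1(F1 − 1) / (2(F2 + 1))`, which stays defined for samples
  without doubletons.
* **Shannon** uses the natural logarithm (nats); a uniform 4-taxon sample
  gives `log(4) ≈ 1.386`.
* **Faith's PD** is *rooted*: the branch path from the observed tips up to
  the tree root is included, so a single observed tip already has positive
  PD.  On a unit-branch star tree, PD of k observed tips is exactly k.
* **Rarefaction** subsamples reads without replacement, one draw per
  sample under a recorded seed.  Samples whose library is below the depth
  are *excluded and listed*, not silently kept at lower depth — matching
  how markedly shallow samples are usually handled in practice.  Default
  depths are 40,000 reads (bacteria) and 39,000 (fungi).

Two-way ANOVA (`value ~ treatment * species`) uses the classical balanced
decomposition; when a cell has fewer than two replicates the interaction
is flagged as not estimable.  A constant response short-circuits to
`F = 0, p = 1` rather than the indeterminate `0/0`.  Because diversity
variances routinely differ across species, group comparisons use Welch's
ANOVA with Games–Howell post-hoc tests: pairwise studentized-range
statistics with Welch–Satterthwaite degrees of freedom.

Compact letter displays are built by insert-and-absorb: start with one
class holding all groups, split every class that contains a significantly
different pair, and absorb classes contained in another.  Letters are
ordered by the class's highest group mean.  (A simpler one-pass greedy
assignment was rejected: it cannot express overlap patterns such as
`a / ab / b / c`, which these data routinely produce.)

## PERMANOVA

The one-way pseudo-F is computed from the partition of summed squared
dissimilarities: `SS_total = Σ d²/n` over all pairs, `SS_within` summed
per group, `R² = SS_among / SS_total`, and
`p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` so that p never reports zero
and has resolution `1/(n_perm + 1)`.  The default 999 permutations give
the customary p = 0.001 floor.  The implementation is checked against
`vegan::adonis2` in the test suite, and its type-I error is calibrated by
simulation under an exchangeable null (nominal 5%, accepted within
3–7%).

## Network inference

Genus-level relative abundances from the non-rarefied tables are filtered
per domain before correlation:

* bacteria: nonzero in ≥ 5 of the group's samples **and** mean relative
  abundance ≥ 0.05% over those samples;
* fungi (sparser and lower-abundance): mean relative abundance ≥ 0.001%,
  with no occurrence gate.

Occurrence is counted within the group's own samples because networks are
built per group.  Spearman's tie-corrected rho is computed for every
retained pair, with two-sided p from the t approximation; genera with
constant abundance are excluded from the correlation family rather than
assigned rho = 0.  Edges must pass **both** gates: `|rho| ≥ 0.65`
(non-strict, as printed) and BH-adjusted `q < 0.05`.  The FDR family is
the candidate-pair set of one network build (one family per group ×
mode); for cross-domain networks only bacteria–fungus pairs are
candidates, so within-domain pairs neither form edges nor dilute the FDR
family, and the resulting graph is bipartite by construction.

Module detection runs the multilevel (Louvain) heuristic on the
unweighted, sign-ignored graph under a fixed seed and reports
Newman–Girvan modularity Q of the returned partition.  Edge signs are
kept for reporting (percent positive edges) but do not enter community
detection or path metrics.  Diameter and average path length are computed
over reachable (within-component) pairs, since modular graphs are often
disconnected.  The test suite verifies Q against a direct evaluation of
the definition and against an exhaustive partition search on graphs of up
to 8 nodes (about 4,100 partitions; beyond that exhaustive search grows
into the millions and adds no further information).

## Core taxa and their contribution

With `k = ceiling(0.10 · N)`, the core set is the union of the top-k
nodes by degree and the top-k by (unweighted shortest-path) betweenness —
the union, because requiring both criteria empties the core in small
networks.  Ties at rank k are broken by the other centrality and then by
lexicographic id; betweenness is rounded to 8 decimals first so that
mathematically tied scores are not separated by floating-point
accumulation order.  `|core| ≤ 2k` always.

For a group's samples, the **taxonomic contribution** is the per-sample
sum of core-genus relative abundances; the **functional contribution**
weights each genus by its total predicted-function load and normalizes by
the community-wide functional total.  Both are reported as mean ± SE
(`sd/√n`) in percent.  For guild-type fungal predictions — one trophic
mode per genus with weight 1 — the functional contribution equals the
taxonomic one identically, which is a useful internal consistency check.

Core-genus reporting across groups is based on the cross-domain
(bacteria–fungi) networks; single-network cores can be computed and
reported separately with the same functions.

## Visitation statistics

The pollen remaining rate for an open-treatment replicate is
`100 · open_i / mean(bagging)` (percent); values above 100 are legitimate.
Rates are compared across species by one-way ANOVA with Tukey HSD after a
Levene homogeneity check.

Because sequencing samples and pollen counts are unpaired, the
species-level association between remaining rate and core-genus function
uses a bootstrap: per iteration, each species' x- and y-replicates are
resampled *independently* with replacement, species means are taken, and
Spearman's rho is computed across species.  With 4 species and no ties,
every drawn rho lies on the 11-value lattice {−1, −0.8, …, 0.8, 1}.  The
95% CI is the percentile interval with inverse-ECDF quantiles, so both
endpoints are members of the empirical distribution.  Default 5,000
iterations.

Cohen's *d* uses the pooled-SD form; dispersions may be supplied as SEs,
converted via `s = se·√n`.  The SE reading of published `mean ± x`
summaries with n = 5 is adopted because only that convention reproduces
the reference effect size (d ≈ −3.07) from the remaining-rate table — the
worked example in the test suite performs exactly this reproduction.
(One published table prints an MC mean of 97.22 where its companion
prints 97.23 ± 0.59; the difference −14.22 is consistent with 97.23, which
is used throughout.)

## The synthetic-data generator

`synth_spec()` describes the emulated study: 4 species (2 self-, 2
cross-pollinated) × 2 treatments × 5 replicates = 40 samples; 150
bacterial and 60 fungal genera (scaled down from the thousands of OTUs in
a real run so the full test suite runs at desk speed); library sizes
uniform on [39,000, 90,000] reads, straddling the rarefaction depths.

Counts come from a **latent Gaussian copula**: per sample, genus
log-intensities are a geometric-decay abundance profile plus
genus-specific species and treatment shifts plus unit-variance noise;
genera in a planted block share a common factor giving pairwise latent
correlation 0.9; intensities are exponentiated and reads drawn
multinomially.  A copula (rather than, say, Dirichlet-multinomial) is
used because pairwise *rank* correlations are then directly plantable,
and Spearman rank correlation is the pipeline's edge statistic.  Fungal
shift SDs (2.0 species / 1.0 treatment, log scale) exceed bacterial ones
(0.6 / 0.3), so fungal communities separate more strongly by group — the
asymmetry consistently reported for pollen microbiomes — and the
simulated fungal PERMANOVA R² exceeds the bacterial one.

The **planted core** is a 12-genus fungal set whose summed intensity
share in each `Cross_open` sample is rescaled to a per-sample target
drawn as N(0.85, 0.08) (truncated to [0.02, 0.98]), so the expected
summed relative abundance is 85% with realistic between-sample spread.
Recovery of this value by `core_contribution()` is part of the acceptance
checks.

The **pollen generator** draws bagging grain counts with CV 5% (no
within-species bagging variance is published; 5% is a realistic bench
value, and it is a spec knob) and open counts so the remaining rate per
species matches the published means/SEs (CA 64.94 ± 1.01, SM 90.04 ±
1.67, LA 83.01 ± 2.87, MC 97.23 ± 0.59).  Calibration is verified over
200 seeds in the tests.  One consequence worth knowing: at these SEs the
SM–LA Tukey contrast sits almost exactly on the 5% critical value, so the
textbook letter split a/b/b/c appears in only about half of simulated
datasets; the robust features (CA lowest and distinct, MC above and
separate from LA) appear in essentially all of them, and the tests assert
those.

### What the generator does and does not emulate

It emulates the design geometry, library-size variation, log-normal-like
abundance decay, plantable rank correlations, group-specific core
dominance, and domain asymmetry in effect sizes.  It does **not** emulate
taxonomic misannotation, chimeras, compositional closure artifacts beyond
multinomial sampling, batch effects, or phylogenetic signal in abundance.
Passing the planted-recovery tests therefore demonstrates correctness of
the estimators on data satisfying the model's assumptions, not robustness
to every real-data pathology.

### Edge-recovery ground truth

The planted-block recovery check uses a *homogeneous* variant of the
default spec (species/treatment shift SDs set to 0) and builds the
network over all 40 samples.  Two reasons.  First, nonzero group shifts
induce genuine correlations between genera that respond to the same
species — those edges are real, not "spurious", so a false-positive count
against them would be meaningless.  Second, at n = 10 samples (one
group), a Spearman rho of exactly 0.65 has an unadjusted p ≈ 0.04: after
BH adjustment over thousands of candidate pairs no edge at the gate can
survive, for any implementation — the per-group builds are simply
underpowered at the planted effect size, which mirrors the small
single-group networks seen in practice.  Over all 40 samples the planted
rho = 0.9 blocks are recovered essentially completely with < 1% spurious
edges.

## Problem sizes and determinism

Everything random takes an explicit integer seed: generators, rarefaction,
permutations, Louvain, bootstrap.  The default validation sizes — 10
generator seeds for edge recovery and core recovery, a 200-graph corpus
(4–12 nodes) for the keystone oracle, 1,000 simulations × 199
permutations for PERMANOVA calibration, 5,000 bootstrap iterations —
were chosen so the complete suite runs in well under a minute on a single
core while leaving Monte-Carlo margins of several standard errors around
every threshold.

## Known limitations

* Spearman p-values use the t approximation, adequate at n ≥ 10 but
  approximate at the minimum supported n = 4.
* Louvain is a heuristic; Q is exact for the returned partition but the
  partition itself is only near-optimal (verified within 0.02 of the
  exhaustive optimum on small graphs).
* The compact letter display is the standard insert-and-absorb
  construction; for pathological non-transitive significance patterns more
  than 26 classes would exhaust the alphabet.
* Functional contributions treat predicted function tables as fixed
  inputs; no uncertainty from the prediction step is propagated.
* PERMANOVA is one-way by design (composite group factor); factorial
  partitions of R² are out of scope.
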