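---
title: "Methods: deep personality networks from consensus NMF biclustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep personality networks from consensus NMF biclustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## The model

phenonet implements a data-driven pipeline for the joint architecture of
temperament and character. Its premise is that personality structure is not
well described by independent trait scores: subgroups of people share
distinctive *configurations* of TCI subscales, subgroups of subjects share
co-occurring SNP alleles, and these subgroups overlap. The pipeline
formalizes this as:

1. **Biclusters ("sets")** — a subgroup of subjects together with the
   subset of features on which they deviate from the typical profile. Sets
   are extracted from nonnegative matrix factorization (NMF) of each
   subjects-by-features matrix: `X ≈ W H` with `W, H ≥ 0`; factor `j`
   yields one candidate set (subjects with high `W[, j]`, features with
   high `H[j, ]`).
2. **Relations** — two sets from different domains are related when they
   share more subjects than chance allows, measured by the exact upper-tail
   hypergeometric probability, Fisher's two-sided exact test, and an
   empirical permutation null. Significance demands the analytic test
   (after Benjamini–Hochberg correction across all pairs) *and* the
   permutation test.
3. **Deep networks** — the bipartite temperament-by-character matrix of
   significant relation weights is itself factorized by NMF at rank
   `k = 3`; each set joins its maximal factor, subjects join the network
   holding the plurality of their membership weight, and networks are
   renamed 1..k by ascending mean well-being.
4. **Integration** — SNP sets and environment sets (biclustered the same
   way) are tested for enrichment in each network's subject pool;
   environment sets are classified as *directly* associated (sharing
   subjects with a network's phenotype sets) or *indirectly* associated
   through a mediating SNP set. Genotype and environment contributions to
   network membership are compared by cross-validated R² of ordinary
   least-squares fits on the network index (1, 2, 3, ordered by mean
   well-being), with each subject's predictor the mean health probability
   of the sets containing it.
5. **Replication** — the pipeline is rerun blind on a second cohort and
   discovery sets are matched to replication sets by shared *features*
   (subjects are not comparable across cohorts), with a permutation test
   on the matched fraction.

## Preprocessing and the membership rule

Two places where the published procedure is underdetermined required
design decisions; both are configurable and both defaults were chosen on
methodological grounds:

* **Baseline removal.** Scored scales (phenotype subscales, ordinal
  environment variables) share a large positive baseline: every subject
  scores well above zero on every subscale. A direct NMF spends its
  leading factor(s) on this flat component and the subject loadings of
  all factors are dominated by it. `derive_sets()` therefore subtracts
  each feature's median and clips at zero before factorizing, so factors
  model *above-typical exceedance*. Genotype dosage (0/1/2 counts of the
  alternate allele) already measures deviation from a zero baseline and
  is factorized raw (`baseline = "none"`).
* **Membership binarization.** A factor's loadings are continuous; a set
  needs a hard membership. The default policy (`"bimodal"`) splits each
  factor's loading vector into a low and a high group by two-means
  clustering and keeps the high group. This self-calibrates to the
  loading scale of each factor. The alternative `"relative_max"` policy
  (keep loadings ≥ 0.5 of the factor maximum) is retained but is fragile:
  a single extreme subject sets the cut for everyone, and in simulation
  it misses half of each planted block.

## Rank selection

For every candidate rank, `select_ranks()` runs several randomly
initialized factorizations, co-clusters subjects by dominant factor, and
scores the rank by the cophenetic correlation between the consensus
dissimilarity and its average-linkage dendrogram (Brunet-style consensus
stability). Ranks at or above the stability threshold (default 0.95) are
retained — the most stable rank always is — and sets are accumulated
across all retained ranks, which is what produces collections of dozens
of fine-grained, partly overlapping sets from a single matrix. (The
source procedure is described as *minimizing* the cophenetic coefficient;
consensus-NMF practice, and this package, retain the *most stable* ranks.
The discrepancy is noted and the threshold is a parameter.)

Deterministic extraction uses NNDSVD initialization (variant "a", zeros
replaced by the matrix mean so multiplicative updates are not locked);
consensus runs use seeded random initialization. The multiplicative
updates minimize the Frobenius error; missing cells are excluded from the
objective with a binary mask, so missingness needs no imputation. The
objective is recorded each iteration and is non-increasing; convergence is
declared when the relative improvement falls below `tol` (default 1e-5).

Network partitioning factorizes a small matrix whose block structure
induces poor local optima under a single deterministic start;
`partition_networks()` therefore restarts from NNDSVD plus 10 seeded
random initializations and keeps the lowest final objective.

## Subject assignment and the unassigned fraction

A subject joins the network holding the plurality (> 50% by default) of
its summed subject-axis weights over that network's sets. A second,
absolute floor realizes the "threshold for significant association":
the winning weight must reach 25% of the median winning weight of that
network's members. Genuine members accumulate weight across several sets
of their network; a background subject swept into one stray bicluster
falls far below the floor. In simulation this keeps the measured
unassigned fraction within about one percentage point of the planted
background rate.

## Health indices

Well-being is membership in the top decile of the product of the three
character scale totals (SD × CO × ST); ill-being is the bottom decile of
SD + CO. Scale totals are sums of subscale columns (TCI convention).
Decile cutpoints are strict: with distinct scores exactly `ceiling(0.1 n)`
subjects are flagged; scores tied at the cutpoint are not flagged, so an
all-ties cohort flags nobody. The two flags are not mutually exclusive and
their overlap is reported. Network comparisons use textbook one-way ANOVA
sums of squares with Tukey's range test via the studentized-range
distribution; both are cross-checked against `stats::aov()` /
`stats::TukeyHSD()` in the test suite. Per-relationship health is the
flagged fraction of the two sets' intersection (configurable), and the
health surface orders sets by average-linkage clustering of pairwise
−log10 shared-subject p-values; interpolation is a rendering concern and
is not performed.

## The synthetic cohort generator

No cohort data are distributed with the package, so `generate_cohort()`
emulates the statistical structure the analysis assumes, with planted
ground truth for recovery scoring. Defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_subjects` | 2000 | cohort size |
| subscales | 16 + 13 | temperament (NS/HA/RD/PS) + character (SD/CO/ST) |
| `n_snps` | 1000 | SNPs, Hardy–Weinberg background, MAF U(0.05, 0.5) |
| `n_env_vars` | 15 | ordinal 0–3 environment variables |
| `n_networks` | 3 | planted near-disjoint networks |
| `effect_size` | 2 | additive shift of planted cells (reference sd = 1) |
| `noise_sd` | 1 | phenotype residual sd (background N(5, sd), clipped at 0) |
| `disjointness` | 0.9 | 1 − shared fraction of per-network feature pools |
| `unassigned_fraction` | 0.05 | pure-background subjects |
| `subject_fraction` | 0.9 | of a network block sampled per planted set |
| `missing_rate` | 0 | MCAR missingness |

Each network owns a disjoint subject block and, per domain, a feature
pool; the `disjointness` dial allocates a slice of each pool that is
shared by all networks. Planted sets sample 90% of their block and 80% of
their pool; overlapping planted cells are elevated once. Genotype
planting redraws planted cells at an allele frequency raised by
`0.2 × effect_size` (capped at 0.95), shifting dosage toward 2.
Environment sets are wired alternately *direct* (subjects from the
network block) and *indirect* (subjects from a mediating planted SNP
set); the wiring and mediator are recorded in the truth. An optional
3-population ancestry confound (`structure_strength`) shifts allele
frequencies on the logit scale to exercise the PC stratification.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real cohorts: linkage disequilibrium, genotyping
error, item-level response processes, non-MCAR missingness, correlated
measurement error across subscales, and effect sizes that vary across
sets. In particular, because all of a network's planted sets draw
subjects from one block, direct and indirect environmental wiring are
confounded at the recovered-set level (an indirect set's subjects also
overlap the block's phenotype sets); the direct/indirect classifier is
therefore unit-tested on constructed collections where the two channels
are separable, and the generator's wiring table is used to verify what
was planted, not to benchmark the classifier's discrimination.

`generate_twin_cohort()` redraws subjects, blocks, and noise while
keeping the planted feature structure and wiring — an independent cohort
measured on the same instruments and variants — and is the basis of the
replication simulations.

## Significance settings

Defaults mirror the analysis the pipeline reimplements: analytic
threshold 1e−5 (after BH correction across all pairs; a raw-threshold
mode exists), 1999 permutations so the smallest attainable empirical p is
5e−4, and the dual analytic-AND-empirical criterion for significance.
Permutations relabel subjects globally (preserving every set's size and
the collection geometry) and can be stratified within ancestry strata.
The empirical p uses the add-one rule, so it is never zero. Relation
weights for partitioning are −log10 hypergeometric p capped at 300.

## Cross-cohort matching

Subjects differ between cohorts, so sets are matched by the
hypergeometric enrichment of shared features over the shared namespace,
greedy best-first one-to-one above a p threshold (default 0.01); an
optimal-assignment alternative solves the maximum-weight bipartite
matching. Pairs whose feature Jaccard reaches 0.9 are acceptable
regardless of p: a set holding nearly the whole namespace cannot be
"enriched" in anything, yet an identical counterpart is plainly a match.
On the 13–16-feature TCI namespaces this power limit is material — a
perfect 4-of-4 subscale overlap in a 13-feature universe only reaches
p ≈ 5e−2 — which is why replication of *relations* is assessed on the
planted collections (where the truth wiring is the oracle) and the
matcher's sensitivity to effect size is demonstrated at small cohort
sizes where recovery genuinely degrades.

## Numerical choices and degenerate inputs

* Hypergeometric tails are computed in log space (`phyper(log.p = TRUE)`);
  values below the smallest positive double are floored there, with the
  exact log10 kept as an attribute.
* A zero matrix factorizes to zero factors with objective 0; a degenerate
  consensus (identical assignments in every run) warns and reports
  cophenetic 1; an empty extraction warns rather than failing silently.
* Ties in subject assignment break by larger total weight, then lower
  network index. kmeans-based splits use fixed extreme-value centers, so
  they are deterministic.
* All randomness flows from a single seed per entry point; stage seeds are
  fixed offsets of the pipeline seed, and rerunning a pipeline with the
  same config reproduces every serialized artifact byte for byte.

## Problem sizes used in the checks

The test suite and the acceptance script run the full study conditions
(n = 2000, 1000 SNPs) for bicluster/network recovery and the twin
replication of relations; rank selection there scans ranks 2–6 with 6
consensus runs (genotype 3–6 with 4 runs in the acceptance script). Null
calibration, matcher power curves, and degenerate-input checks use
cohorts of 80–500 subjects with proportionally reduced SNP counts and
permutation counts of 199–999 — sizes at which the distributional
statements under test (uniformity, error rates, monotone trends) are
already well resolved.

## Known limitations

* NMF multiplicative updates find local optima; restarts mitigate this
  for the small relation matrix but data-matrix factorizations use one
  deterministic start per rank, and pathological inputs could yield poor
  sets at a stable-looking rank.
* The hypergeometric relation test conditions on set sizes; it does not
  model the selection of sets by the upstream NMF, so analytic p-values
  near the significance boundary should be read jointly with the
  permutation p (which does preserve the collection geometry).
* Mediation here is set-theoretic (a significant two-hop overlap chain),
  not causal; no mediation estimand is computed.
* Cross-validated R² on an ordinal 1/2/3 outcome treats the network index
  as numeric, as in the source analysis; it is a rough benchmark, not a
  heritability estimate.
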