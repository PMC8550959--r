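# phenonet

Deep phenotypic, genotypic, and environmental networks of personality
from consensus NMF biclustering.

## The problem

Temperament (Novelty Seeking, Harm Avoidance, Reward Dependence,
Persistence) and character (Self-directedness, Cooperativeness,
Self-transcendence) are usually analyzed as independent trait scores.
But subgroups of people share distinctive *configurations* of TCI
subscales, subgroups share co-occurring SNP alleles, and these subgroups
overlap. phenonet is for researchers who want to recover that joint
architecture from cohort data: it uncovers temperament and character
biclusters ("sets"), organizes their shared-subject relations into a
small number of near-disjoint phenotypic networks, associates genotype
and environment sets with those networks, quantifies health differences
between them, and tests whether the whole structure replicates in an
independent cohort.

## The method

For a nonnegative subjects × features matrix `X`, NMF factorizes
`X ≈ W H` (`W, H ≥ 0`, multiplicative updates, masked objective for
missing cells). Each factor yields one bicluster: the subjects with high
loadings in its `W` column and the features with high loadings in its
`H` row (two-means split of the loading vector by default). Ranks are
chosen by consensus: for each candidate rank, repeated random-start runs
are co-clustered and the rank is scored by the cophenetic correlation of
the consensus matrix; sets accumulate across all stable ranks.

Two sets A and B over a cohort of size `N` are related when their
shared-subject count `o` is improbable under the hypergeometric law,

    P(X >= o), X ~ Hypergeom(N, |A|, |B|),

confirmed by Fisher's two-sided exact test and a subject-relabeling
permutation null (significance = BH-corrected analytic p <= 1e-5 AND
empirical p <= 5e-4). The temperament × character matrix of
-log10 p relation weights is itself NMF-partitioned at rank 3; each set
joins its maximal factor, each subject joins the network holding the
plurality of its membership weight, and networks are numbered 1..3 by
ascending mean well-being (top decile of SD × CO × ST; ill-being is the
bottom decile of SD + CO). SNP sets and environment sets are tested for
enrichment in each network's subject pool (with optional ancestry-PC
stratification of the permutations), environment sets split into direct
and SNP-mediated (indirect) associations, and genotype/environment
contributions to network membership are compared by tenfold
cross-validated R². Replication reruns everything blind on a second
cohort and matches sets across cohorts by shared features.

No cohort data ship with the package; a synthetic-cohort generator with
planted biclusters, networks, and environment wiring
(`generate_cohort()`, `generate_twin_cohort()`) defines the reference
conditions and provides ground truth for every recovery claim.

## Worked example

```r
library(phenonet)

coh <- generate_cohort(cohort_config(seed = 1))   # 2000 subjects
res <- run_pipeline(coh$phenotype, coh$genotype, coh$environment,
                    pipeline_config(seed = 1, k_range_genotype = 3:6,
                                    n_runs = 4))
res
#> pipeline_result: 20 temperament sets, 14 character sets, 97 significant relations
#> network_partition: k = 3; 20 source sets, 14 target sets; 2000 subjects (5.9% unassigned)

adjusted_rand_index(res$partition$subject_labels,
                    coh$truth$subject_labels)
#> [1] 0.973011
res$variance_well
#> variance_report [well-being]: CV R2 genotype 0.790, environment 0.566, joint 0.809 (10 folds)
```

Reading the output: the pipeline accumulated 20 temperament and 14
character sets across the stable NMF ranks; 97 of the 280 set pairs
share significantly many subjects; the three networks recovered from
that relation graph agree with the planted subject partition at ARI 0.97
with 5.9% of subjects unassigned (5% pure background was planted); and
set-level health of the SNP sets containing a subject explains ~79% of
the out-of-fold variance in network membership, with environment adding
little beyond genotype — the same qualitative pattern the pipeline is
designed to expose.

The same steps, written out stage by stage with tables under
`results/`, are in `analysis/01_simulate.R` … `analysis/06_replication.R`
(run them in order from the repository root).

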