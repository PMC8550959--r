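#!/usr/bin/env Rscript
# Simulate the discovery cohort and an independent twin (replication)
# cohort at the default study conditions: 2000 subjects, 16 temperament +
# 13 character TCI subscales, 1000 SNPs, 15 environmental variables, three
# planted networks (effect size 2, residual sd 1, disjointness 0.9, 5%
# unassigned background). Writes all matrices and the planted truth under
# results/data/.

suppressPackageStartupMessages(library(phenonet))
seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

coh <- generate_cohort(cohort_config(seed = seed))
twin <- generate_twin_cohort(coh$truth, seed = seed + 101)

write_feature_matrix(coh$phenotype, "results/data/discovery_phenotype.tsv")
write_feature_matrix(coh$environment, "results/data/discovery_environment.tsv")
write_plink(coh$genotype, "results/data/discovery_genotype")
write_truth(coh$truth, "results/data/discovery_truth.json")
write_feature_matrix(twin$phenotype, "results/data/twin_phenotype.tsv")
write_feature_matrix(twin$environment, "results/data/twin_environment.tsv")
write_plink(twin$genotype, "results/data/twin_genotype")
write_truth(twin$truth, "results/data/twin_truth.json")

cat(sprintf(
  "discovery: %d subjects, %d planted sets, %.1f%% background\n",
  nrow(coh$phenotype$values), length(coh$truth$planted_sets),
  100 * mean(coh$truth$subject_labels == 0)))
cat("twin cohort shares the planted feature structure; subjects are new\n")
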