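#!/usr/bin/env Rscript
# Genotype and environment integration: SNP and environment set
# collections by NMF, hypergeometric + permutation association of SNP sets
# with the phenotypic networks, direct/indirect (SNP-mediated) environment
# associations, and tenfold cross-validated variance in network membership
# explained by genotype and environment set health.

suppressPackageStartupMessages(library(phenonet))
seed <- 1

gen <- load_genotypes("results/data/discovery_genotype.ped")
env <- read_feature_matrix("results/data/discovery_environment.tsv",
                           domain = "environment")
phen <- load_phenotypes("results/data/discovery_phenotype.tsv")
sct <- read_set_collection("results/temperament_sets.json")
scc <- read_set_collection("results/character_sets.json")
part <- jsonlite::read_json("results/partition.json", simplifyVector = TRUE)
p <- structure(list(k = part$k,
                    source_labels = unlist(part$source_labels),
                    target_labels = unlist(part$target_labels),
                    subject_labels = as.integer(part$subject_labels),
                    unassigned_fraction = part$unassigned_fraction,
                    network_order = part$network_order, seed = part$seed),
               class = "network_partition")
h <- compute_indices(phen)

snp <- derive_feature_sets(gen, k_range = 3:6, n_runs = 4, seed = seed + 29)
envs <- derive_feature_sets(env, k_range = 2:5, n_runs = 4, seed = seed + 37)
write_set_collection(snp, "results/snp_sets.json")
write_set_collection(envs, "results/env_sets.json")
cat(sprintf("%d SNP sets, %d environment sets\n", length(snp), length(envs)))

sa <- associate_sets_with_networks(snp, p, alpha = 1e-5, n_perm = 999,
                                   perm_alpha = 1e-3, seed = seed + 31)
print(sa)
write.table(sa$tests, "results/snp_network_assoc.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

er <- env_associations(envs, snp, list(sct, scc), p, sa, alpha = 1e-5,
                       n_perm = 999, perm_alpha = 1e-3, seed = seed + 41)
print(er)
write.table(er$report, "results/env_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (outcome in c("ill", "well")) {
  vr <- variance_explained(p, snp, envs, h, outcome, folds = 10,
                           seed = seed + 43)
  print(vr)
}
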