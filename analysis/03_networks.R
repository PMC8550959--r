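#!/usr/bin/env Rscript
# Relate temperament and character sets by shared subjects (hypergeometric
# + Fisher + permutation null, BH-corrected), partition the bipartite
# relation graph into 3 networks by NMF, assign subjects by weighted
# plurality, order networks by mean well-being, and quantify disjointness.

suppressPackageStartupMessages(library(phenonet))
seed <- 1

sct <- read_set_collection("results/temperament_sets.json")
scc <- read_set_collection("results/character_sets.json")
phen <- load_phenotypes("results/data/discovery_phenotype.tsv")

g <- relate_collections(sct, scc, alpha = 1e-5, n_perm = 1999,
                        perm_alpha = 5e-4, seed = seed + 19)
write_relation_graph(g, "results/phenotype_relations.tsv")
cat(sprintf("%d of %d set pairs significantly related\n",
            sum(g$relations$significant), nrow(g$relations)))

h <- compute_indices(phen)
p <- partition_networks(build_relation_matrix(g), k = 3, seed = seed + 23)
p <- assign_subjects(p, list(sct, scc))
p <- order_networks_by_wellbeing(p, h)
write_partition(p, "results/partition.json")

sizes <- table(factor(p$subject_labels, levels = 0:3))
cat(sprintf("network sizes 1/2/3: %d/%d/%d; %.1f%% unassigned\n",
            sizes[2], sizes[3], sizes[4],
            100 * p$unassigned_fraction))
ds <- disjointness_stats(p, list(temperament = sct, character = scc))
write.table(ds, "results/disjointness.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("max pairwise shared-subject percentage:",
    round(max(ds$pct_shared_subjects), 2), "\n")

truth <- read_truth("results/data/discovery_truth.json")
cat(sprintf("subject-network ARI vs planted truth: %.3f\n",
            adjusted_rand_index(p$subject_labels, truth$subject_labels)))
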