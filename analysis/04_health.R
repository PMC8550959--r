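#!/usr/bin/env Rscript
# Health indices (top decile of SD x CO x ST = well-being; bottom decile of
# SD + CO = ill-being), set-level health probabilities, one-way ANOVA with
# Tukey HSD across the three networks, and the ordered health-surface
# matrices of the temperament-character relation graph.

suppressPackageStartupMessages(library(phenonet))

phen <- load_phenotypes("results/data/discovery_phenotype.tsv")
sct <- read_set_collection("results/temperament_sets.json")
scc <- read_set_collection("results/character_sets.json")
g <- relate_collections(sct, scc, alpha = 1e-5, n_perm = 1999,
                        perm_alpha = 5e-4, seed = 20)
part <- jsonlite::read_json("results/partition.json", simplifyVector = TRUE)
p <- structure(list(k = part$k,
                    source_labels = unlist(part$source_labels),
                    target_labels = unlist(part$target_labels),
                    subject_labels = as.integer(part$subject_labels),
                    unassigned_fraction = part$unassigned_fraction,
                    network_order = part$network_order, seed = part$seed),
               class = "network_partition")

h <- compute_indices(phen)
print(h)
hdf <- data.frame(subject = seq_along(h$well_being),
                  product_score = h$product_score, sum_score = h$sum_score,
                  well_being = h$well_being, ill_being = h$ill_being)
write.table(hdf, "results/health_indices.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (outcome in c("well", "ill")) {
  cmp <- compare_networks(p, h, list(sct, scc), outcome = outcome,
                          level = "sets")
  cat(sprintf("[%s-being, set level] ", outcome)); print(cmp)
  s <- health_surface(g, h, outcome)
  write.table(s$surface,
              sprintf("results/health_surface_%s.tsv", outcome),
              sep = "\t", quote = FALSE, col.names = NA)
}
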