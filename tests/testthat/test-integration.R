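partition_from_labels <- function(labels, k = 3) {
  structure(list(k = as.integer(k),
                 source_labels = stats::setNames(integer(0), character(0)),
                 target_labels = stats::setNames(integer(0), character(0)),
                 subject_labels = as.integer(labels),
                 unassigned_fraction = mean(labels == 0),
                 network_order = seq_len(k), seed = 1L),
            class = "network_partition")
}

test_that("unstructured genotypes give weak leading PCs and no strata", {
  set.seed(15)
  maf <- runif(300, 0.05, 0.5)
  dose <- matrix(rbinom(400 * 300, 2, rep(maf, each = 400)), 400,
                 dimnames = list(NULL, paste0("rs", 1:300)))
  st <- compute_ancestry_pcs(feature_matrix(dose, "genotype"),
                             n_pcs = 3, seed = 1)
  # leading eigenvalue of pure noise sits at the Marchenko-Pastur edge
  # (1 + sqrt(p/n))^2 / p of the total variance; allow 10% slack
  mp_edge <- (1 + sqrt(300 / 400))^2 / 300
  expect_lt(st$var_explained[1], 1.1 * mp_edge)
  # the forced 3-way split has only the weak silhouette of isotropic noise
  sil <- cluster_silhouette(st$strata, dist(st$scores))
  expect_lt(sil, 0.3)
  # contrast: genuine 3-population structure separates far better
  coh <- generate_cohort(cohort_config(n_subjects = 400, n_snps = 300,
                                       structure_strength = 2, seed = 15))
  st2 <- compute_ancestry_pcs(coh$genotype, n_pcs = 3, seed = 1)
  sil2 <- cluster_silhouette(st2$strata, dist(st2$scores))
  expect_gt(sil2, sil + 0.2)
})

test_that("a planted 3-population structure is recovered by the strata", {
  coh <- generate_cohort(cohort_config(n_subjects = 500, n_snps = 400,
                                       structure_strength = 2, seed = 16))
  st <- compute_ancestry_pcs(coh$genotype, n_pcs = 3, seed = 2)
  expect_gte(adjusted_rand_index(st$strata, coh$truth$populations), 0.9)
})

test_that("n_pcs = 0 passes through as a single stratum", {
  coh <- small_cohort(seed = 17)
  st <- compute_ancestry_pcs(coh$genotype, n_pcs = 0)
  expect_equal(unique(st$strata), 1L)
  expect_equal(ncol(st$scores), 0)
})

test_that("excessive per-SNP missingness is an error naming the SNPs", {
  coh <- small_cohort(seed = 18)
  g <- coh$genotype
  g$values[1:250, "rs1"] <- NA
  expect_error(compute_ancestry_pcs(g), "rs1")
})

test_that("derive_feature_sets enforces its domain and names sets E_/G_", {
  coh <- small_cohort(seed = 19)
  expect_error(derive_feature_sets(coh$phenotype), "genotype or environment")
  sc <- derive_feature_sets(coh$environment, k_range = 2:3, n_runs = 3,
                            seed = 4)
  expect_true(all(grepl("^E_\\d+_\\d+$", set_ids(sc))))
})

test_that("a set equal to a network's pool is maximally enriched", {
  labels <- rep(c(1L, 2L, 3L, 0L), times = c(30, 30, 30, 10))
  p <- partition_from_labels(labels)
  sc <- collection_from_sets(list(which(labels == 2L)), 100, "genotype")
  sa <- associate_sets_with_networks(sc, p, n_perm = 199,
                                     perm_alpha = 0.01, alpha = 1e-3,
                                     seed = 5)
  t2 <- sa$tests[sa$tests$network == 2, ]
  expect_equal(t2$overlap, 30L)
  # p equals the hypergeometric minimum for those margins (enumeration)
  expect_equal(t2$p_hypergeom, enum_hyper_upper(30, 30, 70, 30),
               tolerance = 1e-12)
  expect_true(t2$significant)
  expect_equal(sa$networks_of_set[["G_9_1"]], 2L)
})

test_that("background-only sets associate with no network", {
  set.seed(6)
  labels <- rep(c(1L, 2L, 3L, 0L), times = c(60, 60, 60, 120))
  p <- partition_from_labels(labels)
  bg <- which(labels == 0L)
  sc <- collection_from_sets(list(sample(bg, 60)), 300, "genotype")
  sa <- associate_sets_with_networks(sc, p, n_perm = 199, seed = 6)
  expect_false(any(sa$tests$significant))
})

test_that("association testing is invariant to subject reordering", {
  set.seed(20)
  labels <- rep(c(1L, 2L, 0L), times = c(40, 40, 20))
  sets <- list(sample(which(labels == 1L), 30),
               sample(100, 25))
  perm <- sample.int(100)
  inv <- integer(100); inv[perm] <- seq_len(100)
  sa1 <- associate_sets_with_networks(
    collection_from_sets(sets, 100, "genotype"),
    partition_from_labels(labels, 2), n_perm = 199, seed = 7)
  sa2 <- associate_sets_with_networks(
    collection_from_sets(lapply(sets, function(s) sort(inv[s])), 100,
                         "genotype"),
    partition_from_labels(labels[perm], 2), n_perm = 199, seed = 7)
  expect_equal(sa1$tests$overlap, sa2$tests$overlap)
  expect_equal(sa1$tests$p_hypergeom, sa2$tests$p_hypergeom)
})

test_that("environment sets classify as direct, indirect, or both", {
  set.seed(8)
  labels <- rep(c(1L, 2L, 0L), times = c(80, 80, 40))
  net1 <- which(labels == 1L)
  p <- partition_from_labels(labels, 2)
  # phenotype set on network 1; its id must carry a network label
  phen_sc <- collection_from_sets(list(net1[1:60]), 200, "character")
  p$target_labels <- stats::setNames(1L, set_ids(phen_sc)[1])
  # SNP set associated with network 1, disjoint from the phenotype set
  snp_subjects <- net1[21:80]
  snp_sc <- collection_from_sets(list(snp_subjects), 200, "genotype")
  sa <- associate_sets_with_networks(snp_sc, p, n_perm = 199,
                                     perm_alpha = 0.01, alpha = 1e-3,
                                     seed = 9)
  expect_true(any(sa$tests$significant))
  # env set A: same subjects as the phenotype set -> direct;
  # env set B: overlaps only subjects outside the phenotype set, inside the
  # SNP set -> indirect only
  env_sc <- collection_from_sets(list(net1[1:60], net1[61:80]), 200,
                                 "environment")
  er <- env_associations(env_sc, snp_sc, list(phen_sc), p, sa,
                         alpha = 1e-3, n_perm = 199, perm_alpha = 0.01,
                         seed = 10)
  rep_a <- er$report[er$report$env_set == "E_9_1", ]
  rep_b <- er$report[er$report$env_set == "E_9_2", ]
  expect_true(rep_a$direct)
  expect_true(rep_b$indirect)
  expect_false(rep_b$direct)
  expect_equal(er$mediators[["E_9_2"]]$snp_set, "G_9_1")
})

test_that("a noiseless linear outcome gives CV R-squared near 1", {
  # construct sets whose health probabilities are exactly the outcome scale
  labels <- rep(1:3, each = 50)
  p <- partition_from_labels(labels)
  h <- list(well_being = c(rep(FALSE, 50), rep(c(FALSE, TRUE), 25),
                           rep(TRUE, 50)),
            ill_being = rep(FALSE, 150))
  sets <- list(1:50, 51:100, 101:150)
  snp_sc <- collection_from_sets(sets, 150, "genotype")
  env_sc <- collection_from_sets(sets, 150, "environment")
  vr <- variance_explained(p, snp_sc, env_sc, h, "well", folds = 10,
                           seed = 11)
  expect_gt(vr$r2["genotype"], 0.999)
  expect_gt(vr$r2["joint"], 0.999)
})

test_that("null predictors explain nothing out of fold", {
  set.seed(12)
  labels <- rep(1:3, each = 60)
  p <- partition_from_labels(labels)
  h <- list(well_being = sample(c(TRUE, FALSE), 180, replace = TRUE),
            ill_being = rep(FALSE, 180))
  r2 <- replicate(10, {
    sets <- lapply(1:6, function(i) sample.int(180, 50))
    vr <- variance_explained(p, collection_from_sets(sets, 180, "genotype"),
                             collection_from_sets(sets, 180, "environment"),
                             h, "well", folds = 5,
                             seed = sample.int(1e6, 1))
    vr$r2["genotype"]
  })
  expect_lt(mean(r2), 0.05)
})

test_that("subjects in no predictor set are mean-imputed and flagged", {
  labels <- rep(1:3, each = 20)
  p <- partition_from_labels(labels)
  h <- list(well_being = rep(c(TRUE, FALSE), 30),
            ill_being = rep(FALSE, 60))
  snp_sc <- collection_from_sets(list(1:40), 60, "genotype")  # 41:60 uncovered
  env_sc <- collection_from_sets(list(1:60), 60, "environment")
  vr <- variance_explained(p, snp_sc, env_sc, h, "well", folds = 5,
                           seed = 13)
  expect_equal(unname(vr$n_imputed["genotype"]), 20L)
  expect_equal(unname(vr$n_imputed["environment"]), 0L)
})

test_that("variance_explained refuses cohorts too small for the folds", {
  p <- partition_from_labels(rep(1:3, each = 5))
  h <- list(well_being = rep(TRUE, 15), ill_being = rep(FALSE, 15))
  sc <- collection_from_sets(list(1:15), 15, "genotype")
  expect_error(variance_explained(p, sc, sc, h, folds = 10), "too few")
})
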