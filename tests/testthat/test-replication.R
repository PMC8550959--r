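feature_collection <- function(feature_sets, domain = "character",
                               cohort_size = 100, offset = 0) {
  subject_sets <- lapply(seq_along(feature_sets), function(i)
    (1:20) + offset)
  collection_from_sets(subject_sets, cohort_size, domain,
                       feature_sets = feature_sets)
}

test_that("a collection matches itself completely", {
  sets <- list(1:5, 6:10, 11:15, c(2, 7, 12))
  A <- feature_collection(sets)
  m <- match_collections(A, A, threshold = 0.05)
  expect_equal(m$matched_fraction, 1)
  expect_equal(m$map$discovery, m$map$replication)
})

test_that("greedy and optimal matchers agree on unambiguous problems", {
  disc <- feature_collection(list(1:6, 7:12, 13:18))
  repl <- feature_collection(list(c(1:5, 19), 7:12, c(13:17, 20)))
  mg <- match_collections(disc, repl, threshold = 0.05, method = "greedy")
  mo <- match_collections(disc, repl, threshold = 0.05, method = "optimal")
  expect_equal(mg$matched_fraction, 1)
  expect_equal(mo$matched_fraction, 1)
  a <- mg$map[order(mg$map$discovery), c(1, 2)]
  b <- mo$map[order(mo$map$discovery), c(1, 2)]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the match map is a partial injection", {
  disc <- feature_collection(list(1:6, c(1:5, 7), 8:12))
  repl <- feature_collection(list(1:6, 8:13))
  m <- match_collections(disc, repl, threshold = 0.05)
  expect_false(any(duplicated(m$map$discovery)))
  expect_false(any(duplicated(m$map$replication)))
  expect_lte(nrow(m$map), 2)
})

test_that("shuffled replication features match at the null rate", {
  set.seed(21)
  universe <- 1:40
  disc_sets <- lapply(1:8, function(i) sample(universe, 8))
  obs_fracs <- replicate(20, {
    repl_sets <- lapply(1:8, function(i) sample(universe, 8))
    match_collections(feature_collection(disc_sets),
                      feature_collection(repl_sets),
                      threshold = 0.01)$matched_fraction
  })
  expect_lt(mean(obs_fracs), 0.2)
})

test_that("disjoint feature namespaces are an error", {
  disc <- feature_collection(list(1:5))
  repl <- feature_collection(list(50:55))
  expect_error(match_collections(disc, repl), "share no features")
})

test_that("identical graphs with identity maps replicate fully", {
  A <- collection_from_sets(list(1:10, 11:20), 50)
  B <- collection_from_sets(list(1:10, 11:20), 50, "temperament")
  g <- relate_collections(A, B, alpha = 0.05, correction = "none",
                          n_perm = 199, perm_alpha = 0.01, seed = 1)
  expect_gt(nrow(significant_relations(g)), 0)
  idmap <- function(sc) structure(
    list(map = data.frame(discovery = set_ids(sc),
                          replication = set_ids(sc),
                          p = 0, stringsAsFactors = FALSE),
         matched_fraction = 1, method = "greedy", threshold = 0.01),
    class = "collection_match")
  expect_equal(match_relations(g, g, idmap(A), idmap(B)), 1)
})

test_that("an empty replication graph replicates nothing", {
  A <- collection_from_sets(list(1:10), 50)
  B <- collection_from_sets(list(1:10), 50, "temperament")
  g <- relate_collections(A, B, alpha = 0.05, correction = "none",
                          n_perm = 199, perm_alpha = 0.01, seed = 1)
  g_empty <- g
  g_empty$relations$significant <- FALSE
  m <- structure(list(map = data.frame(discovery = "C_9_1",
                                       replication = "C_9_1", p = 0,
                                       stringsAsFactors = FALSE),
                      matched_fraction = 1, method = "greedy",
                      threshold = 0.01),
                 class = "collection_match")
  expect_equal(match_relations(g, g_empty, m, m), 0)
})

test_that("an unbeatable matched fraction attains the add-one bound", {
  sets <- list(1:5, 6:10, 11:15)
  disc <- feature_collection(sets)
  pt <- replication_permutation_test(1, disc, disc, n_perm = 199, seed = 3)
  expect_equal(pt$p, 1 / 200)
  expect_true(all(pt$null_fractions <= 1))
})

test_that("a null-level matched fraction is not called significant", {
  set.seed(22)
  disc <- feature_collection(lapply(1:6, function(i) sample(1:30, 6)))
  repl <- feature_collection(lapply(1:6, function(i) sample(1:30, 6)))
  obs <- match_collections(disc, repl, threshold = 0.05)$matched_fraction
  pt <- replication_permutation_test(obs, disc, repl, n_perm = 199,
                                     seed = 4, threshold = 0.05)
  expect_gt(pt$p, 0.05)
})

test_that("the pipeline is deterministic end to end", {
  coh <- generate_cohort(cohort_config(n_subjects = 250, n_snps = 60,
                                       snp_pool_size = 10, seed = 41))
  cfg <- pipeline_config(seed = 41, k_range_phenotype = 2:4,
                         k_range_genotype = 3:4, k_range_environment = 2:3,
                         n_runs = 3, n_perm = 199, perm_alpha = 0.01,
                         alpha = 1e-3, folds = 5)
  r1 <- run_pipeline(coh$phenotype, coh$genotype, coh$environment, cfg)
  r2 <- run_pipeline(coh$phenotype, coh$genotype, coh$environment, cfg)
  expect_identical(r1$temperament_sets, r2$temperament_sets)
  expect_identical(r1$phen_graph$relations, r2$phen_graph$relations)
  expect_identical(r1$partition$subject_labels, r2$partition$subject_labels)
  expect_identical(r1$variance_well$r2, r2$variance_well$r2)
  # serialized artifacts byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_pipeline_result(r1, d1)
  write_pipeline_result(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("pipeline errors carry the failing stage's name", {
  coh <- generate_cohort(cohort_config(n_subjects = 120, n_snps = 30,
                                       snp_pool_size = 8, seed = 42))
  bad <- coh$phenotype
  bad$scales <- NULL
  expect_error(run_pipeline(bad, config = pipeline_config(seed = 1)),
               "\\[stage split_phenotype\\]")
})

test_that("twin cohorts replicate the discovery sets by features", {
  coh <- generate_cohort(cohort_config(n_subjects = 500, n_snps = 100,
                                       snp_pool_size = 15, seed = 43))
  twin <- generate_twin_cohort(coh$truth, seed = 44)
  sc_d <- derive_sets(split_phenotype(coh$phenotype)$temperament,
                      k_range = 2:4, n_runs = 3, seed = 5)
  sc_r <- derive_sets(split_phenotype(twin$phenotype)$temperament,
                      k_range = 2:4, n_runs = 3, seed = 6)
  m <- match_collections(sc_d, sc_r, threshold = 0.05)
  expect_gt(m$matched_fraction, 0.6)
  pt <- replication_permutation_test(m$matched_fraction, sc_d, sc_r,
                                     n_perm = 199, seed = 7,
                                     threshold = 0.05)
  expect_lt(pt$p, 0.05)
})
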