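make_graph <- function(rel_df, A, B) {
  structure(list(relations = rel_df, source = A, target = B,
                 cohort_size = A$cohort_size, alpha = 1e-5,
                 perm_alpha = 5e-4, correction = "BH", n_perm = 199L,
                 seed = 1L),
            class = "relation_graph")
}

test_that("relation matrices weight edges as documented", {
  A <- collection_from_sets(list(1:10, 11:20), 50)
  B <- collection_from_sets(list(1:10, 21:30), 50, "temperament")
  rel <- data.frame(source = c("C_9_1", "C_9_2"), target = c("T_9_1", "T_9_2"),
                    overlap = c(10L, 0L), n_source = c(10L, 10L),
                    n_target = c(10L, 10L),
                    p_hypergeom = c(1e-10, 1e-305), p_fisher = c(1e-10, 1),
                    p_adjusted = c(1e-10, 1e-305), p_empirical = c(0.005, 1),
                    significant = c(TRUE, TRUE), stringsAsFactors = FALSE)
  g <- make_graph(rel, A, B)
  M <- build_relation_matrix(g, "neglog10")
  expect_equal(M["C_9_1", "T_9_1"], 10)
  expect_equal(M["C_9_2", "T_9_2"], 300)   # capped below 1e-300
  expect_equal(sum(M > 0), 2)
  expect_equal(sum(build_relation_matrix(g, "binary")), 2)
  expect_equal(build_relation_matrix(g, "overlap")["C_9_1", "T_9_1"], 10)
})

test_that("a graph with no significant relation cannot be partitioned", {
  A <- collection_from_sets(list(1:10), 50)
  B <- collection_from_sets(list(11:20), 50, "temperament")
  rel <- data.frame(source = "C_9_1", target = "T_9_1", overlap = 0L,
                    n_source = 10L, n_target = 10L, p_hypergeom = 1,
                    p_fisher = 1, p_adjusted = 1, p_empirical = 1,
                    significant = FALSE, stringsAsFactors = FALSE)
  expect_error(build_relation_matrix(make_graph(rel, A, B)), "all zero")
})

test_that("perfectly block-diagonal relation matrices partition exactly", {
  M <- matrix(0, 9, 12, dimnames = list(paste0("C_9_", 1:9),
                                        paste0("T_9_", 1:12)))
  truth_src <- rep(1:3, each = 3); truth_tgt <- rep(1:3, each = 4)
  for (i in 1:9) for (j in 1:12)
    if (truth_src[i] == truth_tgt[j]) M[i, j] <- 50
  p <- partition_networks(M, 3, seed = 1)
  expect_equal(adjusted_rand_index(p$source_labels, truth_src), 1)
  expect_equal(adjusted_rand_index(p$target_labels, truth_tgt), 1)
})

test_that("partitioning validates rank bounds and nonnegativity", {
  M <- matrix(1, 3, 3)
  expect_error(partition_networks(M, 1), "k must be")
  expect_error(partition_networks(M, 4), "rank bound")
  expect_error(partition_networks(-M, 2), "nonnegative")
})

test_that("subjects follow their sets' networks; isolated subjects drop", {
  A <- collection_from_sets(list(1:10, 21:30), 40)
  B <- collection_from_sets(list(1:10, 21:30), 40, "temperament")
  M <- matrix(0, 2, 2, dimnames = list(set_ids(A), set_ids(B)))
  M[1, 1] <- 10; M[2, 2] <- 10
  p <- partition_networks(M, 2, seed = 1)
  p <- assign_subjects(p, list(A, B), min_weight = 0)
  lab <- p$subject_labels
  # subjects in sets of exactly one network are assigned to it
  expect_length(unique(lab[1:10]), 1)
  expect_length(unique(lab[21:30]), 1)
  expect_true(unique(lab[1:10]) != unique(lab[21:30]))
  # subjects in no set are unassigned
  expect_true(all(lab[c(11:20, 31:40)] == 0))
  expect_equal(p$unassigned_fraction, 0.5)
})

test_that("plurality ties break deterministically by weight then index", {
  A <- collection_from_sets(list(1:2, 1:2), 4)
  M <- matrix(0, 2, 2, dimnames = list(set_ids(A), c("X", "Y")))
  p <- structure(list(k = 2L,
                      source_labels = stats::setNames(1:2, set_ids(A)),
                      target_labels = stats::setNames(integer(0),
                                                      character(0)),
                      subject_labels = NULL,
                      unassigned_fraction = NA_real_,
                      network_order = 1:2, seed = 1L),
                 class = "network_partition")
  p <- assign_subjects(p, list(A), min_membership = 0.4, min_weight = 0)
  # equal weight in both networks: share = 0.5 > 0.4, tie -> network 1
  expect_true(all(p$subject_labels[1:2] == 1L))
})

test_that("network ordering by well-being relabels consistently", {
  A <- collection_from_sets(list(1:10, 11:20), 20)
  B <- collection_from_sets(list(1:10, 11:20), 20, "temperament")
  M <- matrix(0, 2, 2, dimnames = list(set_ids(A), set_ids(B)))
  M[1, 1] <- 10; M[2, 2] <- 10
  p <- partition_networks(M, 2, seed = 1)
  p <- assign_subjects(p, list(A, B), min_weight = 0)
  h <- list(well_being = c(rep(TRUE, 10), rep(FALSE, 10)),
            ill_being = rep(FALSE, 20))
  p2 <- order_networks_by_wellbeing(p, h)
  # subjects 1:10 are the well-being-rich group -> highest label k = 2
  expect_true(all(p2$subject_labels[1:10] == 2L))
  expect_true(all(p2$subject_labels[11:20] == 1L))
  expect_setequal(p2$network_order, 1:2)
  # unassigned zeros must be preserved untouched by the relabeling
  p$subject_labels[5] <- 0L
  p3 <- order_networks_by_wellbeing(p, h)
  expect_equal(p3$subject_labels[5], 0L)
  expect_true(all(p3$subject_labels[6:10] == 2L))
})

test_that("disjointness statistics report pairwise sharing percentages", {
  A <- collection_from_sets(list(1:10, 11:20, 21:30, 31:40), 40)
  p <- structure(list(k = 2L,
                      source_labels = stats::setNames(c(1L, 1L, 2L, 2L),
                                                      set_ids(A)),
                      target_labels = stats::setNames(integer(0),
                                                      character(0)),
                      subject_labels = NULL, unassigned_fraction = NA_real_,
                      network_order = 1:2, seed = 1L),
                 class = "network_partition")
  ds <- disjointness_stats(p, list(character = A))
  expect_equal(ds$pct_shared_sets, 0)
  expect_equal(ds$pct_shared_subjects, 0)
  # multi-network association labels: 1 of 4 sets shared between networks
  assoc <- list(character = list(C_9_1 = 1L, C_9_2 = c(1L, 2L),
                                 C_9_3 = 2L, C_9_4 = 2L))
  ds2 <- disjointness_stats(p, list(character = A),
                            association_labels = assoc)
  expect_equal(ds2$pct_shared_sets, 100 * 1 / 4)
})

test_that("one set shared among 50 reads as 2 percent", {
  sets <- lapply(1:50, function(i) ((i - 1) * 4 + 1):(i * 4))
  A <- collection_from_sets(sets, 200)
  ids <- set_ids(A)
  nets <- as.list(rep(1:2, each = 25)); names(nets) <- ids
  nets[[1]] <- c(1L, 2L)   # one set in both networks
  p <- structure(list(k = 2L,
                      source_labels = stats::setNames(rep(1:2, each = 25),
                                                      ids),
                      target_labels = stats::setNames(integer(0),
                                                      character(0)),
                      subject_labels = NULL, unassigned_fraction = NA_real_,
                      network_order = 1:2, seed = 1L),
                 class = "network_partition")
  ds <- disjointness_stats(p, list(character = A),
                           association_labels = list(character = nets))
  expect_equal(ds$pct_shared_sets, 2)
})

test_that("the adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  set.seed(3)
  a <- sample(1:3, 3000, replace = TRUE)
  b <- sample(1:3, 3000, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})

test_that("end-to-end planted networks are recovered on a small cohort", {
  coh <- generate_cohort(cohort_config(n_subjects = 600, n_snps = 60,
                                       snp_pool_size = 10, seed = 31))
  res <- run_pipeline(coh$phenotype,
                      config = pipeline_config(seed = 31, n_perm = 499,
                                               perm_alpha = 2e-3,
                                               include_genotype = FALSE,
                                               include_environment = FALSE))
  ari <- adjusted_rand_index(res$partition$subject_labels,
                             coh$truth$subject_labels)
  expect_gt(ari, 0.85)
  expect_equal(res$partition$k, 3)
})
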