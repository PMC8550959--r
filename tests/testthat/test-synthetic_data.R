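test_that("cohort generation is deterministic given the seed", {
  a <- small_cohort(seed = 7)
  b <- small_cohort(seed = 7)
  expect_identical(a$phenotype$values, b$phenotype$values)
  expect_identical(a$genotype$values, b$genotype$values)
  expect_identical(a$environment$values, b$environment$values)
  expect_identical(a$truth$planted_sets, b$truth$planted_sets)
  c <- small_cohort(seed = 8)
  expect_false(identical(a$phenotype$values, c$phenotype$values))
})

test_that("config validation rejects bad counts, fractions and MAF ranges", {
  expect_error(cohort_config(n_subjects = 0), "positive")
  expect_error(cohort_config(disjointness = 1.2), "fractions")
  expect_error(cohort_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(cohort_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(
    cohort_config(sets_per_domain_per_network = c(temperament = 2)),
    "sets_per_domain_per_network")
})

test_that("infeasible feature sizing raises an explicit error", {
  expect_error(generate_cohort(cohort_config(n_subjects = 100, n_snps = 20,
                                             snp_pool_size = 40,
                                             disjointness = 1)),
               "infeasible sizing")
})

test_that("planted blocks are shifted by effect_size over background", {
  coh <- generate_cohort(cohort_config(n_subjects = 300, n_snps = 100,
                                       snp_pool_size = 15, effect_size = 2,
                                       noise_sd = 1, seed = 5))
  X <- coh$phenotype$values
  nt <- 16
  planted_mask <- matrix(FALSE, nrow(X), nt)
  for (s in phenonet:::planted_sets_of(coh$truth, "temperament"))
    planted_mask[s$subjects, s$features] <- TRUE
  Xt <- X[, seq_len(nt)]
  diff <- mean(Xt[planted_mask]) - mean(Xt[!planted_mask])
  se <- sqrt(stats::var(Xt[planted_mask]) / sum(planted_mask) +
             stats::var(Xt[!planted_mask]) / sum(!planted_mask))
  expect_lt(abs(diff - 2), 3 * se)
})

test_that("zero-noise, fully disjoint cohorts are exactly separable", {
  coh <- generate_cohort(cohort_config(n_subjects = 120, n_snps = 60,
                                       snp_pool_size = 10, noise_sd = 0,
                                       missing_rate = 0, disjointness = 1,
                                       seed = 2))
  X <- coh$phenotype$values
  # background cells are exactly the baseline; planted exactly baseline + 2
  expect_setequal(unique(as.vector(X)), c(5, 7))
  for (s in phenonet:::planted_sets_of(coh$truth,
                                       c("temperament", "character"))) {
    off <- if (s$domain == "temperament") 0 else 16
    block <- X[s$subjects, off + s$features, drop = FALSE]
    expect_true(all(block == 7))
  }
})

test_that("with full disjointness planted feature pools never overlap", {
  coh <- generate_cohort(cohort_config(n_subjects = 200, n_snps = 200,
                                       disjointness = 1, seed = 3))
  for (dom in c("temperament", "character", "genotype", "environment")) {
    sets <- phenonet:::planted_sets_of(coh$truth, dom)
    nets <- split(sets, vapply(sets, `[[`, integer(1), "network"))
    feats <- lapply(nets, function(ss) unique(unlist(lapply(ss, `[[`,
                                                            "features"))))
    for (i in seq_along(feats)) for (j in seq_along(feats))
      if (i < j) expect_length(intersect(feats[[i]], feats[[j]]), 0)
  }
})

test_that("feature sharing between networks decreases with disjointness", {
  shared_frac <- function(d) {
    coh <- generate_cohort(cohort_config(n_subjects = 100, n_snps = 200,
                                         disjointness = d, seed = 11))
    sets <- phenonet:::planted_sets_of(coh$truth, "genotype")
    nets <- split(sets, vapply(sets, `[[`, integer(1), "network"))
    feats <- lapply(nets, function(ss) unique(unlist(lapply(ss, `[[`,
                                                            "features"))))
    pairs <- utils::combn(length(feats), 2)
    mean(vapply(seq_len(ncol(pairs)), function(c2) {
      a <- feats[[pairs[1, c2]]]; b <- feats[[pairs[2, c2]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1)))
  }
  fr <- vapply(c(0, 0.25, 0.5, 0.75, 1), shared_frac, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
  expect_gt(fr[1], 0)
  expect_equal(fr[5], 0)
})

test_that("non-planted genotype background follows Hardy-Weinberg", {
  coh <- generate_cohort(cohort_config(n_subjects = 2000, seed = 9))
  bg_subj <- which(coh$truth$subject_labels == 0)
  planted_snps <- unique(unlist(lapply(
    phenonet:::planted_sets_of(coh$truth, "genotype"), `[[`, "features")))
  # background subjects on any SNP are never elevated; test a SNP sample
  snps <- setdiff(seq_len(ncol(coh$genotype$values)), planted_snps)[1:50]
  n_out <- 0
  for (j in snps) {
    g <- coh$genotype$values[bg_subj, j]
    q <- mean(g) / 2                       # MAF estimate
    exp_freq <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(g + 1, nbins = 3)
    se <- sqrt(length(g) * exp_freq * (1 - exp_freq))
    n_out <- n_out + any(abs(obs - length(g) * exp_freq) > 4 * se)
  }
  expect_lte(n_out, 3)   # 4-sigma outliers should be rare
})

test_that("phenotype scale metadata partitions subscales into 7 scales", {
  coh <- small_cohort(seed = 1)
  sc <- coh$phenotype$scales
  expect_length(sc, 29)
  expect_setequal(unique(sc), c("NS", "HA", "RD", "PS", "SD", "CO", "ST"))
  counts <- table(sc)
  expect_equal(sum(counts), 29)
})

test_that("each subject belongs to at most one planted network", {
  coh <- small_cohort(seed = 4)
  labels <- coh$truth$subject_labels
  expect_true(all(labels %in% 0:3))
  for (s in coh$truth$planted_sets)
    expect_true(all(labels[s$subjects] == s$network))
})

test_that("missingness is applied at the configured MCAR rate", {
  coh <- generate_cohort(cohort_config(n_subjects = 500, n_snps = 200,
                                       missing_rate = 0.1, seed = 6))
  for (m in list(coh$phenotype, coh$genotype, coh$environment)) {
    rate <- mean(is.na(m$values))
    expect_gt(rate, 0.07); expect_lt(rate, 0.13)
  }
})

test_that("truth serialization round-trips losslessly", {
  coh <- small_cohort(seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(coh$truth, path)
  back <- read_truth(path)
  expect_equal(back$planted_sets, coh$truth$planted_sets)
  expect_identical(back$subject_labels, coh$truth$subject_labels)
  expect_equal(back$config[order(names(back$config))],
               coh$truth$config[order(names(coh$truth$config))])
  # 3 networks x 4 domains x 2 sets each
  expect_length(back$planted_sets, 24)
})

test_that("an empty truth round-trips as empty", {
  empty <- structure(list(planted_sets = list(),
                          subject_labels = integer(0),
                          populations = integer(0),
                          config = unclass(cohort_config())),
                     class = "synthetic_truth")
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(empty, path)
  back <- read_truth(path)
  expect_length(back$planted_sets, 0)
  expect_length(back$subject_labels, 0)
})

test_that("malformed truth files fail with a parse error", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json ]", path)
  expect_error(read_truth(path), "malformed")
  writeLines('{"subject_labels": [1]}', path)
  expect_error(read_truth(path), "missing key")
})

test_that("twin cohorts keep planted features but redraw subjects", {
  coh <- small_cohort(seed = 5)
  twin <- generate_twin_cohort(coh$truth, seed = 99)
  a <- coh$truth$planted_sets; b <- twin$truth$planted_sets
  expect_equal(vapply(a, `[[`, character(1), "id"),
               vapply(b, `[[`, character(1), "id"))
  same_feat <- mapply(function(x, y) identical(x$features, y$features), a, b)
  expect_true(all(same_feat))
  same_subj <- mapply(function(x, y) identical(x$subjects, y$subjects), a, b)
  expect_false(all(same_subj))
})
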