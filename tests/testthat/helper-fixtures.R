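# Small deterministic fixtures shared across test files.

small_cohort <- function(seed = 1, n = 300, ...) {
  generate_cohort(cohort_config(n_subjects = n, n_snps = 100,
                                snp_pool_size = 15, seed = seed, ...))
}

# a set_collection built directly from a list of subject-index vectors
collection_from_sets <- function(subject_sets, cohort_size,
                                 domain = "character",
                                 feature_sets = NULL) {
  bics <- lapply(seq_along(subject_sets), function(i) {
    subj <- subject_sets[[i]]
    feat <- if (is.null(feature_sets)) i else feature_sets[[i]]
    list(id = sprintf("%s_9_%d", toupper(substr(domain, 1, 1)), i),
         domain = domain,
         subjects = as.integer(subj), subject_ids = paste0("S", subj),
         features = as.integer(feat), feature_ids = paste0("F", feat),
         subject_weights = rep(1, length(subj)),
         feature_weights = rep(1, length(feat)),
         rank = 9L, factor = i)
  })
  set_collection(bics, cohort_size = cohort_size, domain = domain)
}

# exact upper-tail hypergeometric by direct pmf enumeration (oracle)
enum_hyper_upper <- function(q, m, n_other, k) {
  upper <- min(m, k)
  if (q > upper) return(0)
  sum(stats::dhyper(q:upper, m, n_other, k))
}

# log-space tail summation oracle built from binomial coefficients only
logsum_hyper_upper <- function(q, m, n_other, k) {
  upper <- min(m, k)
  if (q > upper) return(0)
  lg <- lchoose(m, q:upper) + lchoose(n_other, k - (q:upper)) -
    lchoose(m + n_other, k)
  mx <- max(lg)
  exp(mx) * sum(exp(lg - mx))
}

# two-sided Fisher by enumeration of all tables with the observed margins
enum_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# a phenotype feature_matrix from explicit SD/CO/ST subscale values
phenotype_from_scores <- function(sd_total, co_total, st_total) {
  n <- length(sd_total)
  vals <- cbind(matrix(1, n, 16), sd_total / 5, sd_total / 5, sd_total / 5,
                sd_total / 5, sd_total / 5,
                co_total / 5, co_total / 5, co_total / 5, co_total / 5,
                co_total / 5,
                st_total / 3, st_total / 3, st_total / 3)
  colnames(vals) <- c(phenonet:::default_temperament_labels(16),
                      phenonet:::default_character_labels(13))
  feature_matrix(vals, "phenotype",
                 phenonet:::scales_from_labels(colnames(vals)))
}

# mean silhouette width of a labeling over a dist object
cluster_silhouette <- function(labels, d) {
  dm <- as.matrix(d)
  n <- length(labels)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    if (!any(own)) return(0)
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(dm[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
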