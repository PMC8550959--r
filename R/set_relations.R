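#' Hypergeometric upper-tail p-value for a set overlap
#'
#' Probability of observing at least `overlap` shared subjects between a set
#' of size `n_source` and a set of size `n_target` drawn without replacement
#' from a cohort of `cohort_size`. Computed in log space so extreme tails
#' (p well below 1e-300 on the natural scale) keep their magnitude; values
#' that underflow double precision are floored at the smallest positive
#' double, with the exact log10 kept in attribute `log10p`.
#'
#' @param overlap observed shared-subject count.
#' @param n_source,n_target set sizes.
#' @param cohort_size total number of subjects.
#' @return p-value in \[0, 1\] with attribute `log10p`.
#' @export
overlap_pvalue <- function(overlap, n_source, n_target, cohort_size) {
  if (any(c(overlap, n_source, n_target, cohort_size) < 0))
    stop("counts must be nonnegative")
  if (overlap > min(n_source, n_target))
    stop("overlap exceeds the smaller set size")
  if (n_source > cohort_size || n_target > cohort_size)
    stop("set sizes exceed the cohort size")
  if (overlap == 0) {
    p <- 1
    attr(p, "log10p") <- 0
    return(p)
  }
  lp <- stats::phyper(overlap - 1, n_source, cohort_size - n_source,
                      n_target, lower.tail = FALSE, log.p = TRUE)
  p <- exp(lp)
  if (p == 0) p <- .Machine$double.xmin
  attr(p, "log10p") <- lp / log(10)
  p
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact two-sided probability: the sum over all tables with the observed
#' margins whose probability does not exceed the observed table's.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return p-value in \[0, 1\].
#' @export
fisher_pvalue <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("table cells must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

# 2x2 overlap table for a pair of sets over one cohort
overlap_table <- function(overlap, n_source, n_target, cohort_size) {
  matrix(c(overlap, n_source - overlap,
           n_target - overlap,
           cohort_size - n_source - n_target + overlap), 2, 2)
}

# sparse cohort x sets membership matrix
membership_matrix <- function(sc) {
  i <- unlist(lapply(sc$biclusters, `[[`, "subjects"))
  j <- rep(seq_along(sc$biclusters),
           vapply(sc$biclusters, function(b) length(b$subjects), integer(1)))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(sc$cohort_size, length(sc$biclusters)),
                       dimnames = list(NULL, set_ids(sc)))
}

#' Empirical permutation p-values for all pairwise overlaps
#'
#' Permutes the subject identities of collection `B` as whole sets (one
#' global relabeling per permutation, preserving every set's size and the
#' collection's internal geometry) and counts how often a permuted overlap
#' reaches the observed one. Add-one correction:
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`, so p is never 0 and the
#' smallest attainable value is `1 / (1 + n_perm)`.
#'
#' @param A,B `set_collection`s over the same cohort.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param strata optional integer vector of ancestry strata (length =
#'   cohort size); permutations then shuffle subjects within strata only.
#' @return matrix of empirical p-values, |A| x |B|, dimnames = set ids.
#' @export
permutation_null <- function(A, B, n_perm = 1999, seed = 1, strata = NULL) {
  stopifnot(inherits(A, "set_collection"), inherits(B, "set_collection"))
  if (A$cohort_size != B$cohort_size)
    stop("collections index different cohorts")
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- A$cohort_size
  MA <- membership_matrix(A)
  MB <- membership_matrix(B)
  obs <- as.matrix(Matrix::crossprod(MA, MB))
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  set.seed(seed)
  for (r in seq_len(n_perm)) {
    perm <- permute_within(n, strata)
    ov <- as.matrix(Matrix::crossprod(MA, MB[perm, , drop = FALSE]))
    exceed <- exceed + (ov >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  dimnames(p) <- dimnames(obs)
  p
}

permute_within <- function(n, strata = NULL) {
  if (is.null(strata)) return(sample.int(n))
  perm <- integer(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    perm[idx] <- idx[sample.int(length(idx))]
  }
  perm
}

#' Relate two set collections by shared subjects
#'
#' Tests every (source, target) pair for subject-overlap enrichment:
#' exact hypergeometric upper tail and two-sided Fisher probability, plus an
#' empirical permutation p-value. A relation is significant when the
#' analytic p (after the configured multiplicity correction) is at or below
#' `alpha` AND the empirical p is at or below `perm_alpha`.
#'
#' @param A,B `set_collection`s over the same cohort (source / target).
#' @param alpha analytic significance level (default 1e-5, applied after
#'   `correction`).
#' @param n_perm permutations for the empirical null (default 1999, so the
#'   smallest attainable empirical p is 5e-4).
#' @param perm_alpha empirical significance threshold (default 5e-4).
#' @param correction `"BH"` (Benjamini-Hochberg across all pairs) or
#'   `"none"` (raw-threshold mode).
#' @param seed integer seed for the permutations.
#' @param strata optional ancestry strata for stratified permutation.
#' @param min_overlap optional floor on the shared-subject count (default
#'   0: no floor).
#' @return object of class `relation_graph`: data.frame `relations`
#'   (source, target, overlap, n_source, n_target, p_hypergeom, p_fisher,
#'   p_adjusted, p_empirical, significant), sorted by p_hypergeom, plus the
#'   settings and collection references.
#' @export
relate_collections <- function(A, B, alpha = 1e-5, n_perm = 1999,
                               perm_alpha = 5e-4,
                               correction = c("BH", "none"),
                               seed = 1, strata = NULL, min_overlap = 0) {
  correction <- match.arg(correction)
  stopifnot(inherits(A, "set_collection"), inherits(B, "set_collection"))
  if (A$cohort_size != B$cohort_size)
    stop("collections index different cohorts")
  if (n_perm < 1 / perm_alpha - 1)
    warning(sprintf(
      "n_perm = %d cannot attain empirical p <= %g (minimum is %g)",
      n_perm, perm_alpha, 1 / (1 + n_perm)))
  n <- A$cohort_size
  ids_a <- set_ids(A); ids_b <- set_ids(B)
  size_a <- vapply(A$biclusters, function(b) length(b$subjects), integer(1))
  size_b <- vapply(B$biclusters, function(b) length(b$subjects), integer(1))
  ov <- as.matrix(Matrix::crossprod(membership_matrix(A),
                                    membership_matrix(B)))
  pairs <- expand.grid(i = seq_along(ids_a), j = seq_along(ids_b))
  p_hyp <- mapply(function(i, j)
    as.numeric(overlap_pvalue(ov[i, j], size_a[i], size_b[j], n)),
    pairs$i, pairs$j)
  p_fis <- mapply(function(i, j)
    fisher_pvalue(overlap_table(ov[i, j], size_a[i], size_b[j], n)),
    pairs$i, pairs$j)
  p_emp <- permutation_null(A, B, n_perm = n_perm, seed = seed,
                            strata = strata)
  p_emp_v <- p_emp[cbind(pairs$i, pairs$j)]
  p_adj <- if (correction == "BH") stats::p.adjust(p_hyp, "BH") else p_hyp
  sig <- p_adj <= alpha & p_emp_v <= perm_alpha &
    ov[cbind(pairs$i, pairs$j)] >= min_overlap
  rel <- data.frame(source = ids_a[pairs$i], target = ids_b[pairs$j],
                    overlap = ov[cbind(pairs$i, pairs$j)],
                    n_source = size_a[pairs$i], n_target = size_b[pairs$j],
                    p_hypergeom = p_hyp, p_fisher = p_fis,
                    p_adjusted = p_adj, p_empirical = p_emp_v,
                    significant = sig, stringsAsFactors = FALSE)
  rel <- rel[order(rel$p_hypergeom, rel$source, rel$target), ]
  rownames(rel) <- NULL
  structure(list(relations = rel, source = A, target = B,
                 cohort_size = n, alpha = alpha, perm_alpha = perm_alpha,
                 correction = correction, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "relation_graph")
}

#' @export
print.relation_graph <- function(x, ...) {
  cat(sprintf(
    "relation_graph: %d pairs tested (%s x %s), %d significant (alpha=%g, %s; empirical<=%g)\n",
    nrow(x$relations), x$source$domain, x$target$domain,
    sum(x$relations$significant), x$alpha, x$correction, x$perm_alpha))
  invisible(x)
}

#' Significant relations of a graph
#' @param g a `relation_graph`.
#' @return the subset of `g$relations` with `significant == TRUE`.
#' @export
significant_relations <- function(g) {
  stopifnot(inherits(g, "relation_graph"))
  g$relations[g$relations$significant, , drop = FALSE]
}

#' Set collection of the planted truth
#'
#' Exposes the planted sets of one domain as a `set_collection`, e.g. as an
#' oracle for recovery scoring or as exact inputs to downstream stages.
#'
#' @param truth a `synthetic_truth`.
#' @param domain planted domain (`"temperament"`, `"character"`,
#'   `"genotype"`, `"environment"`).
#' @return a `set_collection` with unit weights.
#' @export
truth_collection <- function(truth, domain) {
  planted <- planted_sets_of(truth, domain)
  if (!length(planted)) stop("no planted sets in domain ", domain)
  sets <- lapply(planted, function(p) {
    list(id = p$id, domain = domain,
         subjects = p$subjects,
         subject_ids = paste0("S", p$subjects),
         features = p$features,
         feature_ids = paste0("F", p$features),
         subject_weights = rep(1, length(p$subjects)),
         feature_weights = rep(1, length(p$features)),
         rank = NA_integer_, factor = NA_integer_)
  })
  set_collection(sets, cohort_size = length(truth$subject_labels),
                 domain = domain,
                 meta = list(source = "planted_truth"))
}
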