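#' Ancestry principal components and strata from genotypes
#'
#' PCA of the centered, standardized dosage matrix (missing cells
#' mean-imputed per SNP, zero-variance SNPs dropped); subjects are
#' stratified by k-means on the leading `n_pcs` PC scores. With
#' `n_pcs = 0` every subject falls in a single stratum (no adjustment).
#'
#' @param gen a genotype [feature_matrix()] (dosage 0/1/2, NA missing).
#' @param n_pcs number of leading PCs (default 3).
#' @param k_strata number of k-means strata (default 3).
#' @param seed integer seed for k-means.
#' @param max_missing maximum tolerated per-SNP missingness (default 0.2).
#' @return object of class `ancestry_strata`: `scores` (subjects x n_pcs),
#'   `strata` (integer per subject), `var_explained` (per retained PC).
#' @export
compute_ancestry_pcs <- function(gen, n_pcs = 3, k_strata = 3, seed = 1,
                                 max_missing = 0.2) {
  stopifnot(inherits(gen, "feature_matrix"))
  X <- gen$values
  miss <- colMeans(is.na(X))
  if (any(miss > max_missing))
    stop("excessive missingness (> ", max_missing, ") in SNPs: ",
         paste(utils::head(colnames(X)[miss > max_missing], 10),
               collapse = ", "))
  n <- nrow(X)
  if (n_pcs == 0) {
    return(structure(list(scores = matrix(0, n, 0),
                          strata = rep(1L, n),
                          var_explained = numeric(0)),
                     class = "ancestry_strata"))
  }
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- mean(X[, j], na.rm = TRUE)
  }
  keep <- apply(X, 2, stats::sd) > 0
  X <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  var_all <- sum(pc$sdev^2)
  scores <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k_strata, nstart = 10)
  structure(list(scores = scores, strata = as.integer(km$cluster),
                 var_explained = pc$sdev[seq_len(ncol(scores))]^2 / var_all),
            class = "ancestry_strata")
}

#' @export
print.ancestry_strata <- function(x, ...) {
  cat(sprintf("ancestry_strata: %d subjects, %d PCs, %d strata\n",
              length(x$strata), ncol(x$scores), length(unique(x$strata))))
  invisible(x)
}

#' Derive genotype or environment set collections
#'
#' Delegates to the NMF biclustering machinery with domain-appropriate
#' defaults; set ids follow the `G_<rank>_<index>` / `E_<rank>_<index>`
#' naming convention.
#'
#' @param X a genotype or environment [feature_matrix()].
#' @param ... overrides forwarded to [derive_sets()] (`k_range`, `n_runs`,
#'   `seed`, thresholds, ...).
#' @return a `set_collection`.
#' @export
derive_feature_sets <- function(X, ...) {
  stopifnot(inherits(X, "feature_matrix"))
  if (!X$domain %in% c("genotype", "environment"))
    stop("derive_feature_sets expects a genotype or environment matrix")
  args <- list(...)
  if (is.null(args$k_range))
    args$k_range <- if (X$domain == "genotype") 2:8 else 2:6
  do.call(derive_sets, c(list(X = X, domain = X$domain), args))
}

#' Associate sets with phenotypic networks
#'
#' Tests every set of a collection for subject-overlap enrichment against
#' each network's assigned subject pool: exact hypergeometric upper tail
#' plus an empirical permutation p (subject labels permuted, within ancestry
#' strata when supplied). A set may associate with several networks.
#'
#' @param sc a `set_collection` (e.g. SNP or environment sets).
#' @param p a `network_partition` with subject labels.
#' @param strata optional `ancestry_strata` (or integer vector) for
#'   stratified permutation.
#' @param alpha analytic threshold after BH correction (default 1e-5).
#' @param n_perm permutations (default 1999).
#' @param perm_alpha empirical threshold (default 5e-4).
#' @param seed integer seed.
#' @return object of class `network_association`: data.frame `tests`
#'   (set, network, overlap, p_hypergeom, p_adjusted, p_empirical,
#'   significant), list `networks_of_set` (set id -> associated networks),
#'   and the k x 1 contingency of associated sets per network.
#' @export
associate_sets_with_networks <- function(sc, p, strata = NULL,
                                         alpha = 1e-5, n_perm = 1999,
                                         perm_alpha = 5e-4, seed = 1) {
  stopifnot(inherits(sc, "set_collection"),
            inherits(p, "network_partition"))
  if (is.null(p$subject_labels))
    stop("partition lacks subject labels; run assign_subjects first")
  if (inherits(strata, "ancestry_strata")) strata <- strata$strata
  n <- length(p$subject_labels)
  if (sc$cohort_size != n) stop("collections index different cohorts")
  net_sets <- lapply(seq_len(p$k), function(net) {
    list(id = sprintf("NET%d", net), domain = "network",
         subjects = which(p$subject_labels == net),
         subject_ids = paste0("S", which(p$subject_labels == net)),
         features = 1L, feature_ids = "network",
         subject_weights = rep(1, sum(p$subject_labels == net)),
         feature_weights = 1, rank = NA_integer_, factor = NA_integer_)
  })
  net_sc <- set_collection(net_sets, cohort_size = n, domain = "network")
  ids <- set_ids(sc)
  sizes <- vapply(sc$biclusters, function(b) length(b$subjects), integer(1))
  net_size <- vapply(net_sets, function(b) length(b$subjects), integer(1))
  ov <- as.matrix(Matrix::crossprod(membership_matrix(sc),
                                    membership_matrix(net_sc)))
  p_emp <- permutation_null(sc, net_sc, n_perm = n_perm, seed = seed,
                            strata = strata)
  grid <- expand.grid(i = seq_along(ids), net = seq_len(p$k))
  p_hyp <- mapply(function(i, net)
    as.numeric(overlap_pvalue(ov[i, net], sizes[i], net_size[net], n)),
    grid$i, grid$net)
  p_adj <- stats::p.adjust(p_hyp, "BH")
  sig <- p_adj <= alpha & p_emp[cbind(grid$i, grid$net)] <= perm_alpha
  tests <- data.frame(set = ids[grid$i], network = grid$net,
                      overlap = ov[cbind(grid$i, grid$net)],
                      n_set = sizes[grid$i], n_network = net_size[grid$net],
                      p_hypergeom = p_hyp, p_adjusted = p_adj,
                      p_empirical = p_emp[cbind(grid$i, grid$net)],
                      significant = sig, stringsAsFactors = FALSE)
  networks_of_set <- lapply(ids, function(id)
    sort(tests$network[tests$set == id & tests$significant]))
  names(networks_of_set) <- ids
  counts <- vapply(seq_len(p$k), function(net)
    sum(vapply(networks_of_set, function(x) net %in% x, logical(1))),
    integer(1))
  structure(list(tests = tests, networks_of_set = networks_of_set,
                 sets_per_network = counts, alpha = alpha,
                 perm_alpha = perm_alpha),
            class = "network_association")
}

#' @export
print.network_association <- function(x, ...) {
  cat(sprintf(
    "network_association: %d sets tested against %d networks; per-network associated sets: %s\n",
    length(x$networks_of_set), length(x$sets_per_network),
    paste(x$sets_per_network, collapse = "/")))
  invisible(x)
}

#' Direct and indirect environmental associations with the networks
#'
#' An environment set is DIRECTLY associated with a network when it
#' significantly shares subjects with a temperament or character set
#' belonging to that network; INDIRECTLY when it significantly shares
#' subjects with a SNP set that itself associates with the network
#' (gene-environment chain, with the SNP set as mediator); BOTH when both
#' hold for at least one network each.
#'
#' @param env_sc environment `set_collection`.
#' @param snp_sc SNP `set_collection`.
#' @param phen_collections list of phenotype `set_collection`s (temperament
#'   and character) whose sets carry network labels under `p`.
#' @param p a `network_partition`.
#' @param snp_assoc `network_association` of the SNP sets (from
#'   [associate_sets_with_networks()]).
#' @param alpha,n_perm,perm_alpha,seed significance settings for the
#'   overlap tests.
#' @param strata optional ancestry strata for stratified permutation.
#' @return object of class `env_association_report`: data.frame `report`
#'   (env_set, direct/indirect/both flags, per-network flags), list
#'   `mediators` (env set -> data.frame of mediating SNP sets and their
#'   networks), and the counts `n_direct`, `n_indirect`, `n_both`.
#' @export
env_associations <- function(env_sc, snp_sc, phen_collections, p, snp_assoc,
                             alpha = 1e-5, n_perm = 1999, perm_alpha = 5e-4,
                             seed = 1, strata = NULL) {
  stopifnot(inherits(env_sc, "set_collection"),
            inherits(snp_sc, "set_collection"),
            inherits(p, "network_partition"),
            inherits(snp_assoc, "network_association"))
  if (inherits(strata, "ancestry_strata")) strata <- strata$strata
  if (inherits(phen_collections, "set_collection"))
    phen_collections <- list(phen_collections)
  env_ids <- set_ids(env_sc)
  k <- p$k
  direct <- matrix(FALSE, length(env_ids), k,
                   dimnames = list(env_ids, NULL))
  # direct: env set x phenotype set overlap, phenotype set labeled by network
  for (sc in phen_collections) {
    g <- relate_collections(env_sc, sc, alpha = alpha, n_perm = n_perm,
                            perm_alpha = perm_alpha, seed = seed,
                            strata = strata)
    labs <- collection_labels(p, sc)
    rel <- significant_relations(g)
    if (nrow(rel)) for (r in seq_len(nrow(rel))) {
      net <- labs[rel$target[r]]
      if (!is.na(net)) direct[rel$source[r], net] <- TRUE
    }
  }
  # indirect: env set x SNP set overlap, SNP set associated with network
  g_snp <- relate_collections(env_sc, snp_sc, alpha = alpha, n_perm = n_perm,
                              perm_alpha = perm_alpha, seed = seed,
                              strata = strata)
  indirect <- matrix(FALSE, length(env_ids), k,
                     dimnames = list(env_ids, NULL))
  mediators <- stats::setNames(vector("list", length(env_ids)), env_ids)
  rel <- significant_relations(g_snp)
  if (nrow(rel)) for (r in seq_len(nrow(rel))) {
    snp_nets <- snp_assoc$networks_of_set[[rel$target[r]]]
    if (length(snp_nets)) {
      indirect[rel$source[r], snp_nets] <- TRUE
      mediators[[rel$source[r]]] <- rbind(
        mediators[[rel$source[r]]],
        data.frame(snp_set = rel$target[r],
                   network = snp_nets, stringsAsFactors = FALSE))
    }
  }
  any_direct <- rowSums(direct) > 0
  any_indirect <- rowSums(indirect) > 0
  report <- data.frame(env_set = env_ids, direct = any_direct,
                       indirect = any_indirect,
                       both = any_direct & any_indirect,
                       stringsAsFactors = FALSE)
  for (net in seq_len(k)) {
    report[[sprintf("direct_net%d", net)]] <- direct[, net]
    report[[sprintf("indirect_net%d", net)]] <- indirect[, net]
  }
  rownames(report) <- NULL
  structure(list(report = report, mediators = mediators,
                 n_direct = sum(any_direct), n_indirect = sum(any_indirect),
                 n_both = sum(any_direct & any_indirect)),
            class = "env_association_report")
}

#' @export
print.env_association_report <- function(x, ...) {
  cat(sprintf(
    "env_association_report: %d direct, %d indirect, %d both (of %d environment sets)\n",
    x$n_direct, x$n_indirect, x$n_both, nrow(x$report)))
  invisible(x)
}

#' Cross-validated variance in network membership explained by set health
#'
#' The outcome is the subject's network index, networks ordered 1..k by
#' ascending mean well-being; unassigned subjects are excluded. Each
#' subject's predictor per domain is the mean set-level health probability
#' (for the chosen outcome) over the sets of that domain containing the
#' subject; subjects in no set of a domain get the grand mean (flagged in
#' the report). Three OLS fits — genotype-only, environment-only, joint —
#' are scored by mean out-of-fold R-squared over `folds` network-stratified
#' cross-validation folds.
#'
#' @param p a `network_partition` with subject labels ordered by
#'   well-being.
#' @param snp_sc,env_sc SNP and environment `set_collection`s.
#' @param h a `health_indices`.
#' @param outcome `"well"` or `"ill"` (which health probability feeds the
#'   predictors).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param aggregate `"mean"` (default) or `"median"` over containing sets.
#' @return object of class `variance_report`: `r2` (named: genotype,
#'   environment, joint), `fold_r2` (folds x 3), `n_imputed` per domain,
#'   `folds`, `seed`, `outcome`.
#' @export
variance_explained <- function(p, snp_sc, env_sc, h,
                               outcome = c("well", "ill"),
                               folds = 10, seed = 1,
                               aggregate = c("mean", "median")) {
  outcome <- match.arg(outcome)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(p, "network_partition"))
  if (is.null(p$subject_labels))
    stop("partition lacks subject labels")
  keep <- which(p$subject_labels > 0)
  if (length(keep) < folds * 5)
    stop("too few assigned subjects for ", folds, "-fold CV")
  y <- as.numeric(p$subject_labels[keep])

  predictor <- function(sc) {
    probs <- vapply(sc$biclusters, function(b)
      set_health_probability(b, h)[[if (outcome == "well") "p_well"
                                    else "p_ill"]],
      numeric(1))
    agg <- if (aggregate == "mean") mean else stats::median
    vals <- rep(NA_real_, length(keep))
    M <- membership_matrix(sc)[keep, , drop = FALSE]
    for (ii in seq_along(keep)) {
      in_sets <- which(M[ii, ] > 0)
      if (length(in_sets)) vals[ii] <- agg(probs[in_sets])
    }
    n_imp <- sum(is.na(vals))
    vals[is.na(vals)] <- mean(vals, na.rm = TRUE)
    list(x = vals, n_imputed = n_imp)
  }
  gx <- predictor(snp_sc)
  ex <- predictor(env_sc)
  dat <- data.frame(y = y, g = gx$x, e = ex$x)

  set.seed(seed)
  fold_id <- integer(length(y))
  for (net in unique(y)) {             # network-stratified folds
    idx <- sample(which(y == net))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  models <- list(genotype = y ~ g, environment = y ~ e, joint = y ~ g + e)
  fold_r2 <- matrix(NA_real_, folds, length(models),
                    dimnames = list(NULL, names(models)))
  for (f in seq_len(folds)) {
    train <- dat[fold_id != f, ]; test <- dat[fold_id == f, ]
    for (m in names(models)) {
      fit <- stats::lm(models[[m]], data = train)
      pred <- stats::predict(fit, newdata = test)
      sse <- sum((test$y - pred)^2)
      sst <- sum((test$y - mean(train$y))^2)
      fold_r2[f, m] <- 1 - sse / sst
    }
  }
  structure(list(r2 = colMeans(fold_r2), fold_r2 = fold_r2,
                 n_imputed = c(genotype = gx$n_imputed,
                               environment = ex$n_imputed),
                 folds = as.integer(folds), seed = as.integer(seed),
                 outcome = outcome),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf(
    "variance_report [%s-being]: CV R2 genotype %.3f, environment %.3f, joint %.3f (%d folds)\n",
    x$outcome, x$r2["genotype"], x$r2["environment"], x$r2["joint"],
    x$folds))
  invisible(x)
}
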