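#' Pipeline configuration
#'
#' Collects every stage's parameters with documented defaults. Unknown
#' names are rejected so config files cannot silently misspell a setting.
#'
#' @param ... overrides of the defaults listed below.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    k_range_phenotype = 2:6,       # candidate NMF ranks, phenotype domains
    k_range_genotype = 3:8,
    k_range_environment = 2:5,
    n_runs = 6,                    # consensus runs per rank
    rank_selection = "cophenetic", # or "all"
    stability_threshold = 0.95,
    subject_policy = "bimodal",    # bicluster membership binarization
    feature_policy = "bimodal",
    subject_threshold = 0.5,       # relative-max fallback thresholds
    feature_threshold = 0.5,
    alpha = 1e-5,                  # analytic significance (after BH)
    correction = "BH",
    n_perm = 1999,                 # permutation count
    perm_alpha = 5e-4,             # empirical significance
    k_networks = 3,
    min_membership = 0.5,          # plurality share for subject assignment
    min_weight = 0.25,             # weight floor vs network median
    folds = 10,                    # CV folds for variance explained
    n_pcs = 0,                     # ancestry PCs (0 = no stratification)
    k_strata = 3,
    include_genotype = TRUE,
    include_environment = TRUE,
    max_iter = 200,
    tol = 1e-5,
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown pipeline_config setting(s): ",
         paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full discovery pipeline on one cohort
#'
#' Orchestrates biclustering of the temperament and character matrices,
#' their shared-subject relation graph, partitioning into k near-disjoint
#' networks, subject assignment, health indices and network comparisons,
#' and (optionally) the genotype/environment integration stages. All
#' randomness derives from `config$seed`; re-running with the same inputs
#' and config reproduces the result exactly.
#'
#' @param phen phenotype [feature_matrix()] with scale metadata.
#' @param gen genotype [feature_matrix()] (or NULL).
#' @param env environment [feature_matrix()] (or NULL).
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_result` with components
#'   `temperament_sets`, `character_sets`, `phen_graph`, `partition`,
#'   `health`, `comparison_well`, `comparison_ill`, and when inputs allow,
#'   `strata`, `snp_sets`, `snp_assoc`, `env_sets`, `env_report`,
#'   `variance_well`, `variance_ill`; plus the `config`.
#' @export
run_pipeline <- function(phen, gen = NULL, env = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list(config = config)
  seed <- config$seed

  ph <- with_stage("split_phenotype", split_phenotype(phen))
  res$temperament_sets <- with_stage("bicluster_temperament",
    derive_sets(ph$temperament, k_range = config$k_range_phenotype,
                n_runs = config$n_runs,
                rank_selection = config$rank_selection,
                stability_threshold = config$stability_threshold,
                subject_policy = config$subject_policy,
                feature_policy = config$feature_policy,
                subject_threshold = config$subject_threshold,
                feature_threshold = config$feature_threshold,
                max_iter = config$max_iter, tol = config$tol,
                seed = seed + 11L))
  res$character_sets <- with_stage("bicluster_character",
    derive_sets(ph$character, k_range = config$k_range_phenotype,
                n_runs = config$n_runs,
                rank_selection = config$rank_selection,
                stability_threshold = config$stability_threshold,
                subject_policy = config$subject_policy,
                feature_policy = config$feature_policy,
                subject_threshold = config$subject_threshold,
                feature_threshold = config$feature_threshold,
                max_iter = config$max_iter, tol = config$tol,
                seed = seed + 13L))

  strata <- NULL
  if (!is.null(gen) && config$n_pcs > 0) {
    res$strata <- with_stage("ancestry_pcs",
      compute_ancestry_pcs(gen, n_pcs = config$n_pcs,
                           k_strata = config$k_strata, seed = seed + 17L))
    strata <- res$strata$strata
  }

  res$phen_graph <- with_stage("relate_phenotypes",
    relate_collections(res$temperament_sets, res$character_sets,
                       alpha = config$alpha, n_perm = config$n_perm,
                       perm_alpha = config$perm_alpha,
                       correction = config$correction,
                       seed = seed + 19L, strata = strata))

  res$health <- with_stage("health_indices", compute_indices(phen))

  res$partition <- with_stage("partition_networks", {
    M <- build_relation_matrix(res$phen_graph)
    p <- partition_networks(M, k = config$k_networks, seed = seed + 23L)
    p <- assign_subjects(p, list(res$temperament_sets, res$character_sets),
                         min_membership = config$min_membership,
                         min_weight = config$min_weight)
    order_networks_by_wellbeing(p, res$health)
  })

  res$comparison_well <- with_stage("compare_networks",
    compare_networks(res$partition, res$health,
                     list(res$temperament_sets, res$character_sets),
                     outcome = "well", level = "sets"))
  res$comparison_ill <- with_stage("compare_networks",
    compare_networks(res$partition, res$health,
                     list(res$temperament_sets, res$character_sets),
                     outcome = "ill", level = "sets"))

  if (!is.null(gen) && config$include_genotype) {
    res$snp_sets <- with_stage("bicluster_genotype",
      derive_feature_sets(gen, k_range = config$k_range_genotype,
                          n_runs = config$n_runs,
                          rank_selection = config$rank_selection,
                          stability_threshold = config$stability_threshold,
                          subject_policy = config$subject_policy,
                          feature_policy = config$feature_policy,
                          subject_threshold = config$subject_threshold,
                          feature_threshold = config$feature_threshold,
                          max_iter = config$max_iter, tol = config$tol,
                          seed = seed + 29L))
    res$snp_assoc <- with_stage("associate_snp_sets",
      associate_sets_with_networks(res$snp_sets, res$partition,
                                   strata = strata, alpha = config$alpha,
                                   n_perm = config$n_perm,
                                   perm_alpha = config$perm_alpha,
                                   seed = seed + 31L))
  }
  if (!is.null(env) && config$include_environment) {
    res$env_sets <- with_stage("bicluster_environment",
      derive_feature_sets(env, k_range = config$k_range_environment,
                          n_runs = config$n_runs,
                          rank_selection = config$rank_selection,
                          stability_threshold = config$stability_threshold,
                          subject_policy = config$subject_policy,
                          feature_policy = config$feature_policy,
                          subject_threshold = config$subject_threshold,
                          feature_threshold = config$feature_threshold,
                          max_iter = config$max_iter, tol = config$tol,
                          seed = seed + 37L))
    if (!is.null(res$snp_assoc))
      res$env_report <- with_stage("env_associations",
        env_associations(res$env_sets, res$snp_sets,
                         list(res$temperament_sets, res$character_sets),
                         res$partition, res$snp_assoc,
                         alpha = config$alpha, n_perm = config$n_perm,
                         perm_alpha = config$perm_alpha,
                         seed = seed + 41L, strata = strata))
  }
  if (!is.null(res$snp_sets) && !is.null(res$env_sets)) {
    res$variance_well <- with_stage("variance_explained",
      variance_explained(res$partition, res$snp_sets, res$env_sets,
                         res$health, outcome = "well",
                         folds = config$folds, seed = seed + 43L))
    res$variance_ill <- with_stage("variance_explained",
      variance_explained(res$partition, res$snp_sets, res$env_sets,
                         res$health, outcome = "ill",
                         folds = config$folds, seed = seed + 47L))
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d temperament sets, %d character sets, %d significant relations\n",
    length(x$temperament_sets), length(x$character_sets),
    sum(x$phen_graph$relations$significant)))
  if (!is.null(x$partition)) print(x$partition)
  invisible(x)
}

# feature-overlap p and Jaccard matrices between two collections over a
# shared namespace
feature_overlap_pvalues <- function(disc, repl, n_features) {
  fd <- lapply(disc$biclusters, `[[`, "feature_ids")
  fr <- lapply(repl$biclusters, `[[`, "feature_ids")
  universe <- union(unlist(fd), unlist(fr))
  if (is.null(n_features)) n_features <- length(universe)
  P <- matrix(1, length(fd), length(fr),
              dimnames = list(set_ids(disc), set_ids(repl)))
  J <- matrix(0, length(fd), length(fr), dimnames = dimnames(P))
  for (i in seq_along(fd)) for (j in seq_along(fr)) {
    ov <- length(intersect(fd[[i]], fr[[j]]))
    P[i, j] <- as.numeric(overlap_pvalue(ov, length(fd[[i]]),
                                         length(fr[[j]]), n_features))
    J[i, j] <- ov / length(union(fd[[i]], fr[[j]]))
  }
  list(P = P, J = J)
}

#' Match discovery sets to replication sets by shared features
#'
#' Subjects are not comparable across cohorts, so cross-cohort matching
#' scores the hypergeometric enrichment of shared FEATURES (subscale or
#' variant ids) over the shared feature namespace. The default matcher is
#' greedy best-first one-to-one: pairs are considered in order of ascending
#' p and accepted while both ends are unmatched and p <= `threshold`.
#' `method = "optimal"` solves the maximum-weight bipartite assignment on
#' -log10 p instead.
#'
#' @param disc,repl `set_collection`s from the discovery / replication
#'   cohort, sharing a feature namespace.
#' @param threshold maximum feature-overlap p for an acceptable match
#'   (default 0.01).
#' @param method `"greedy"` or `"optimal"` (igraph maximum-weight bipartite
#'   matching).
#' @param jaccard_min pairs whose feature Jaccard reaches this value are
#'   acceptable regardless of their enrichment p (default 0.9). Near-
#'   universal sets leave the hypergeometric test without power — a set
#'   holding almost the whole namespace cannot be "enriched" — yet an
#'   (almost) identical counterpart is plainly a match.
#' @param n_features size of the shared feature namespace; defaults to the
#'   union of feature ids seen in either collection.
#' @return object of class `collection_match`: data.frame `map`
#'   (discovery, replication, p), `matched_fraction` (matched discovery
#'   sets / all discovery sets), `method`, `threshold`.
#' @export
match_collections <- function(disc, repl, threshold = 0.01,
                              method = c("greedy", "optimal"),
                              jaccard_min = 0.9, n_features = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(disc, "set_collection"),
            inherits(repl, "set_collection"))
  fd <- unlist(lapply(disc$biclusters, `[[`, "feature_ids"))
  fr <- unlist(lapply(repl$biclusters, `[[`, "feature_ids"))
  if (!length(intersect(fd, fr)))
    stop("collections share no features; cannot match")
  ov <- feature_overlap_pvalues(disc, repl, n_features)
  P <- ov$P
  ids_d <- rownames(P); ids_r <- colnames(P)
  cand <- which(P <= threshold | ov$J >= jaccard_min, arr.ind = TRUE)
  map <- data.frame(discovery = character(0), replication = character(0),
                    p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cand)) {
    if (method == "greedy") {
      ord <- order(P[cand])
      used_d <- logical(length(ids_d)); used_r <- logical(length(ids_r))
      for (idx in ord) {
        i <- cand[idx, 1]; j <- cand[idx, 2]
        if (used_d[i] || used_r[j]) next
        used_d[i] <- TRUE; used_r[j] <- TRUE
        map <- rbind(map, data.frame(discovery = ids_d[i],
                                     replication = ids_r[j],
                                     p = P[i, j], stringsAsFactors = FALSE))
      }
    } else {
      edges <- cbind(cand[, 1], length(ids_d) + cand[, 2])
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, length(ids_d)), rep(TRUE, length(ids_r))),
        edges = as.vector(t(edges)))
      igraph::E(g)$weight <- -log10(pmax(P[cand], 1e-300))
      mm <- igraph::max_bipartite_match(g)$matching
      for (i in seq_along(ids_d)) {
        j <- mm[i]
        if (!is.na(j))
          map <- rbind(map, data.frame(
            discovery = ids_d[i], replication = ids_r[j - length(ids_d)],
            p = P[i, j - length(ids_d)], stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(map = map,
                 matched_fraction = nrow(map) / length(ids_d),
                 method = method, threshold = threshold),
            class = "collection_match")
}

#' @export
print.collection_match <- function(x, ...) {
  cat(sprintf("collection_match [%s]: %.0f%% matched (%d pairs)\n",
              x$method, 100 * x$matched_fraction, nrow(x$map)))
  invisible(x)
}

#' Fraction of discovery relations replicated
#'
#' A discovery relation (significant source-target pair) is matched iff
#' both endpoint sets are matched across cohorts and the corresponding
#' replication pair is itself significant in the replication graph.
#'
#' @param disc_g,repl_g `relation_graph`s from the two cohorts.
#' @param source_match,target_match `collection_match`es for the source and
#'   target collections.
#' @return matched fraction in \[0, 1\] (0 when the discovery graph has no
#'   significant relations).
#' @export
match_relations <- function(disc_g, repl_g, source_match, target_match) {
  stopifnot(inherits(disc_g, "relation_graph"),
            inherits(repl_g, "relation_graph"))
  disc_rel <- significant_relations(disc_g)
  if (!nrow(disc_rel)) return(0)
  repl_rel <- significant_relations(repl_g)
  repl_pairs <- paste(repl_rel$source, repl_rel$target)
  smap <- stats::setNames(source_match$map$replication,
                          source_match$map$discovery)
  tmap <- stats::setNames(target_match$map$replication,
                          target_match$map$discovery)
  matched <- vapply(seq_len(nrow(disc_rel)), function(r) {
    s <- smap[disc_rel$source[r]]; t <- tmap[disc_rel$target[r]]
    !is.na(s) && !is.na(t) && paste(s, t) %in% repl_pairs
  }, logical(1))
  mean(matched)
}

#' Permutation significance of a matched fraction
#'
#' Permutes the feature labels of the replication collection (one global
#' relabeling of the shared namespace per permutation), recomputes the
#' matched fraction each time, and returns the add-one empirical p of the
#' observed fraction.
#'
#' @param observed_fraction the matched fraction to test.
#' @param disc,repl the two `set_collection`s.
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @param threshold,method forwarded to [match_collections()].
#' @return list: `p` (empirical, never 0), `null_fractions`.
#' @export
replication_permutation_test <- function(observed_fraction, disc, repl,
                                         n_perm = 200, seed = 1,
                                         threshold = 0.01,
                                         method = "greedy") {
  if (n_perm < 100) stop("n_perm must be >= 100")
  universe <- union(unlist(lapply(disc$biclusters, `[[`, "feature_ids")),
                    unlist(lapply(repl$biclusters, `[[`, "feature_ids")))
  set.seed(seed)
  null_fractions <- vapply(seq_len(n_perm), function(r) {
    relabel <- stats::setNames(sample(universe), universe)
    perm_repl <- repl
    perm_repl$biclusters <- lapply(repl$biclusters, function(b) {
      b$feature_ids <- unname(relabel[b$feature_ids])
      b
    })
    match_collections(disc, perm_repl, threshold = threshold,
                      method = method)$matched_fraction
  }, numeric(1))
  p <- (1 + sum(null_fractions >= observed_fraction)) / (1 + n_perm)
  list(p = p, null_fractions = null_fractions)
}
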