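#' Weighted relation matrix of a bipartite relation graph
#'
#' Builds the source-sets x target-sets matrix over the significant
#' relations of `g`. Nonsignificant pairs are 0.
#'
#' @param g a `relation_graph`.
#' @param weighting `"neglog10"` (-log10 of the hypergeometric p, capped),
#'   `"overlap"` (shared-subject count) or `"binary"`.
#' @param cap cap for the -log10 weighting (default 300).
#' @return numeric matrix with set-id dimnames.
#' @export
build_relation_matrix <- function(g,
                                  weighting = c("neglog10", "overlap",
                                                "binary"),
                                  cap = 300) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(g, "relation_graph"))
  rel <- significant_relations(g)
  M <- matrix(0, length(g$source), length(g$target),
              dimnames = list(set_ids(g$source), set_ids(g$target)))
  if (nrow(rel)) {
    w <- switch(weighting,
                neglog10 = pmin(cap, -log10(pmax(rel$p_hypergeom,
                                                 10^(-cap)))),
                overlap = rel$overlap,
                binary = rep(1, nrow(rel)))
    M[cbind(rel$source, rel$target)] <- w
  }
  if (all(M == 0))
    stop("relation matrix is all zero: nothing to partition")
  M
}

#' Partition a bipartite relation matrix into k networks
#'
#' NMF of the relation matrix at rank `k` (bidirectional clustering): every
#' source set is assigned to its maximal `W` factor and every target set to
#' its maximal `H` factor. Sets with no significant relation (all-zero rows
#' or columns) are left unassigned (label `NA`).
#'
#' The factorization is restarted from the deterministic NNDSVD
#' initialization plus `n_restarts` random initializations, keeping the run
#' with the lowest final objective — relation matrices are small, and the
#' restarts avoid the local optima block-structured matrices induce.
#'
#' @param M nonnegative relation matrix from [build_relation_matrix()].
#' @param k number of networks (default 3).
#' @param seed integer seed.
#' @param n_restarts random restarts besides the deterministic start
#'   (default 10).
#' @return object of class `network_partition`: `k`, `source_labels` and
#'   `target_labels` (named integer vectors over set ids), placeholders for
#'   subject labels (filled by [assign_subjects()]) and network names
#'   (filled by [order_networks_by_wellbeing()]).
#' @export
partition_networks <- function(M, k = 3, seed = 1, n_restarts = 10) {
  if (k < 2) stop("k must be >= 2")
  if (any(M < 0)) stop("relation matrix must be nonnegative")
  if (k > min(dim(M)))
    stop(sprintf("k = %d exceeds the matrix rank bound %d", k, min(dim(M))))
  fp <- nmf_factorize(M, k, seed = seed, init = "nndsvd", max_iter = 500)
  for (r in seq_len(n_restarts)) {
    cand <- nmf_factorize(M, k, seed = seed + r, init = "random",
                          max_iter = 500)
    if (utils::tail(cand$objective, 1) < utils::tail(fp$objective, 1))
      fp <- cand
  }
  src <- max.col(fp$W, ties.method = "first")
  tgt <- apply(fp$H, 2, which.max)
  src[rowSums(M) == 0] <- NA_integer_
  tgt[colSums(M) == 0] <- NA_integer_
  names(src) <- rownames(M); names(tgt) <- colnames(M)
  structure(list(k = as.integer(k),
                 source_labels = src, target_labels = tgt,
                 subject_labels = NULL, unassigned_fraction = NA_real_,
                 network_order = seq_len(k), seed = as.integer(seed)),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("network_partition: k = %d; %d source sets, %d target sets",
              x$k, length(x$source_labels), length(x$target_labels)))
  if (!is.null(x$subject_labels))
    cat(sprintf("; %d subjects (%.1f%% unassigned)",
                length(x$subject_labels), 100 * x$unassigned_fraction))
  cat("\n")
  invisible(x)
}

# network label of each set of a collection under a partition
collection_labels <- function(p, sc) {
  ids <- set_ids(sc)
  lab <- rep(NA_integer_, length(ids))
  src <- intersect(ids, names(p$source_labels))
  tgt <- intersect(ids, names(p$target_labels))
  lab[match(src, ids)] <- p$source_labels[src]
  lab[match(tgt, ids)] <- p$target_labels[tgt]
  names(lab) <- ids
  lab
}

#' Assign subjects to networks by weighted plurality of set memberships
#'
#' Each subject's membership weight in a network is the sum of its
#' subject-axis weights over that network's sets (across the supplied
#' collections). The subject is assigned to the network holding the largest
#' share, provided the share exceeds `min_membership` of the subject's
#' total weight; subjects in no set, or failing the share threshold, are
#' unassigned. Ties are broken by the larger total weight, then by the
#' lower network index.
#'
#' A second, absolute criterion realizes the "threshold for significant
#' association" that keeps background subjects out: the subject's weight in
#' the winning network must reach `min_weight` times the median winning
#' weight of that network's preliminarily assigned members. Genuine
#' members accumulate weight across several of a network's sets, so the
#' floor is self-calibrating per network; a subject swept into a single
#' stray bicluster falls well below it.
#'
#' @param p a `network_partition`.
#' @param collections list of `set_collection`s whose set ids appear in the
#'   partition (typically the temperament and character collections).
#' @param min_membership minimum plurality share (default 0.5).
#' @param min_weight weight floor as a fraction of the network's median
#'   member weight (default 0.25; 0 disables it).
#' @return the partition, with `subject_labels` (0 = unassigned) and
#'   `unassigned_fraction` filled in.
#' @export
assign_subjects <- function(p, collections, min_membership = 0.5,
                            min_weight = 0.25) {
  stopifnot(inherits(p, "network_partition"))
  if (inherits(collections, "set_collection"))
    collections <- list(collections)
  n <- collections[[1]]$cohort_size
  Wnet <- matrix(0, n, p$k)
  for (sc in collections) {
    stopifnot(sc$cohort_size == n)
    labs <- collection_labels(p, sc)
    for (i in seq_along(sc$biclusters)) {
      net <- labs[i]
      if (is.na(net)) next
      b <- sc$biclusters[[i]]
      Wnet[b$subjects, net] <- Wnet[b$subjects, net] + b$subject_weights
    }
  }
  tot <- rowSums(Wnet)
  best <- max.col(Wnet, ties.method = "first")
  share <- ifelse(tot > 0, Wnet[cbind(seq_len(n), best)] / tot, 0)
  lab <- ifelse(tot > 0 & share > min_membership, best, 0L)
  if (min_weight > 0 && any(lab > 0)) {
    med <- vapply(seq_len(p$k), function(net) {
      members <- lab == net
      if (!any(members)) return(0)
      stats::median(Wnet[members, net])
    }, numeric(1))
    win_w <- Wnet[cbind(seq_len(n), best)]
    lab[lab > 0 & win_w < min_weight * med[best]] <- 0L
  }
  p$subject_labels <- as.integer(lab)
  p$unassigned_fraction <- mean(lab == 0)
  p$membership_weights <- Wnet
  p
}

#' Order networks by mean well-being
#'
#' Renames the networks 1..k in ascending order of the mean well-being flag
#' of their member subjects (1 = lowest well-being, k = highest), relabeling
#' sets and subjects consistently. The ordering is a permutation of 1..k
#' and is invariant to how the NMF factors happened to be numbered.
#'
#' @param p a `network_partition` with subject labels.
#' @param h a `health_indices` object (see [compute_indices()]).
#' @return the partition with relabeled networks and a `network_order`
#'   record (old label of each new network 1..k).
#' @export
order_networks_by_wellbeing <- function(p, h) {
  stopifnot(inherits(p, "network_partition"))
  if (is.null(p$subject_labels))
    stop("assign subjects before ordering networks (assign_subjects)")
  mean_wb <- vapply(seq_len(p$k), function(net) {
    members <- which(p$subject_labels == net)
    if (!length(members)) return(Inf)
    mean(h$well_being[members])
  }, numeric(1))
  ord <- order(mean_wb)             # old labels in ascending well-being
  relabel <- match(seq_len(p$k), ord)
  remap <- function(x) {
    y <- x
    sel <- !is.na(x) & x != 0
    y[sel] <- relabel[x[sel]]
    y
  }
  p$source_labels <- stats::setNames(remap(p$source_labels),
                                     names(p$source_labels))
  p$target_labels <- stats::setNames(remap(p$target_labels),
                                     names(p$target_labels))
  p$subject_labels <- as.integer(remap(p$subject_labels))
  p$membership_weights <- p$membership_weights[, ord, drop = FALSE]
  p$network_order <- ord
  p
}

#' Pairwise sharing of sets and subjects between networks
#'
#' For each unordered network pair and each supplied collection: the
#' percentage of that domain's sets appearing in both networks' associated
#' collections, and likewise for subjects. With hard (single-label) set
#' assignments the set sharing is 0 by construction unless
#' `association_labels` supplies multi-network associations (a named list:
#' set id -> integer vector of associated networks, as produced by
#' [associate_sets_with_networks()]).
#'
#' @param p a `network_partition`.
#' @param collections named list of `set_collection`s.
#' @param association_labels optional list (by collection name) of
#'   set-id -> networks associations to use instead of the hard labels.
#' @return data.frame: domain, network_a, network_b, pct_shared_sets,
#'   pct_shared_subjects.
#' @export
disjointness_stats <- function(p, collections, association_labels = NULL) {
  stopifnot(inherits(p, "network_partition"))
  if (inherits(collections, "set_collection"))
    collections <- stats::setNames(list(collections), collections[[1]]$domain)
  if (is.null(names(collections)))
    names(collections) <- vapply(collections, `[[`, character(1), "domain")
  out <- list()
  pairs <- utils::combn(p$k, 2)
  for (nm in names(collections)) {
    sc <- collections[[nm]]
    ids <- set_ids(sc)
    if (!is.null(association_labels) && !is.null(association_labels[[nm]])) {
      nets_of_set <- association_labels[[nm]]
    } else {
      hard <- collection_labels(p, sc)
      nets_of_set <- lapply(seq_along(ids), function(i)
        if (is.na(hard[i])) integer(0) else hard[i])
      names(nets_of_set) <- ids
    }
    subj_of_net <- lapply(seq_len(p$k), function(net) {
      member_sets <- ids[vapply(ids, function(id)
        net %in% nets_of_set[[id]], logical(1))]
      unique(unlist(lapply(sc$biclusters[match(member_sets, ids)],
                           `[[`, "subjects")))
    })
    for (c2 in seq_len(ncol(pairs))) {
      a <- pairs[1, c2]; b <- pairs[2, c2]
      in_a <- vapply(ids, function(id) a %in% nets_of_set[[id]], logical(1))
      in_b <- vapply(ids, function(id) b %in% nets_of_set[[id]], logical(1))
      denom_sets <- sum(in_a | in_b)
      shared_sets <- sum(in_a & in_b)
      sa <- subj_of_net[[a]]; sb <- subj_of_net[[b]]
      denom_subj <- length(union(sa, sb))
      shared_subj <- length(intersect(sa, sb))
      out[[length(out) + 1L]] <- data.frame(
        domain = nm, network_a = a, network_b = b,
        pct_shared_sets = if (denom_sets) 100 * shared_sets / denom_sets else 0,
        pct_shared_subjects =
          if (denom_subj) 100 * shared_subj / denom_subj else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Adjusted Rand Index between two labelings
#'
#' Standard chance-corrected agreement between two partitions of the same
#' items; 1 for identical partitions (up to label renaming), ~0 for
#' independent ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return the ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
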