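#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative subjects x features matrix `X ~ W %*% H` at rank
#' `k`, minimizing the Frobenius reconstruction error. Missing cells are
#' excluded from the objective via a binary mask in the update rules
#' (weighted multiplicative updates), so no imputation is forced on the
#' caller. The objective is tracked per iteration and is non-increasing.
#'
#' @param X nonnegative numeric matrix or [feature_matrix()]; NAs allowed.
#' @param k factorization rank, `1 <= k <= min(dim(X))`.
#' @param seed integer seed (used by the random initialization).
#' @param max_iter maximum number of multiplicative updates.
#' @param tol relative objective-change convergence threshold.
#' @param init `"nndsvd"` (deterministic, SVD-based, zeros filled with the
#'   matrix mean) or `"random"` (uniform, for consensus runs).
#' @return object of class `factor_pair`: nonnegative `W` (subjects x k),
#'   `H` (k x features), per-iteration `objective`, `k`, `seed`, `init`,
#'   `iterations`, `converged`.
#' @export
nmf_factorize <- function(X, k, seed = 1, max_iter = 200, tol = 1e-5,
                          init = c("nndsvd", "random")) {
  init <- match.arg(init)
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- as.matrix(X)
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative input at cell (%d, %d): NMF requires X >= 0",
                 neg[1, 1], neg[1, 2]))
  if (k < 1 || k > min(dim(X)))
    stop(sprintf("rank k = %d out of range [1, %d]", k, min(dim(X))))

  has_na <- anyNA(X)
  M <- NULL
  if (has_na) {
    M <- !is.na(X)
    X[!M] <- 0
    storage.mode(M) <- "double"
  }
  eps <- .Machine$double.eps

  if (all(X == 0)) {
    W <- matrix(0, nrow(X), k); H <- matrix(0, k, ncol(X))
    return(structure(list(W = W, H = H, k = as.integer(k), objective = 0,
                          seed = as.integer(seed), init = init,
                          iterations = 0L, converged = TRUE),
                     class = "factor_pair"))
  }

  set.seed(seed)
  if (init == "nndsvd") {
    wh <- nndsvd_init(X, k)
  } else {
    scale0 <- sqrt(mean(X) / k)
    wh <- list(W = matrix(stats::runif(nrow(X) * k), ncol = k) * scale0,
               H = matrix(stats::runif(k * ncol(X)), nrow = k) * scale0)
  }
  W <- wh$W; H <- wh$H

  obj <- numeric(max_iter)
  prev <- Inf
  iter <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    WH <- W %*% H
    if (has_na) WH <- WH * M
    W <- W * (X %*% t(H)) / (WH %*% t(H) + eps)
    WH <- W %*% H
    if (has_na) WH <- WH * M
    H <- H * (t(W) %*% X) / (t(W) %*% WH + eps)
    WH <- W %*% H
    if (has_na) WH <- WH * M
    obj[iter] <- sqrt(sum((X - WH)^2))
    if (is.finite(prev) &&
        (prev - obj[iter]) < tol * max(prev, eps)) {
      converged <- TRUE
      break
    }
    prev <- obj[iter]
  }
  structure(list(W = W, H = H, k = as.integer(k),
                 objective = obj[seq_len(iter)],
                 seed = as.integer(seed), init = init,
                 iterations = iter, converged = converged),
            class = "factor_pair")
}

#' @export
print.factor_pair <- function(x, ...) {
  cat(sprintf("factor_pair: rank %d, %d x %d, %d iterations, objective %.4g\n",
              x$k, nrow(x$W), ncol(x$H), x$iterations,
              utils::tail(x$objective, 1)))
  invisible(x)
}

# Nonnegative double SVD initialization (Boutsidis & Gallopoulos), variant
# "a": zeros are replaced by the matrix mean so multiplicative updates are
# not locked at zero.
nndsvd_init <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  W <- matrix(0, nrow(X), k); H <- matrix(0, k, ncol(X))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
      n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        sigma <- n_up * n_vp
        if (sigma > 0) {
          W[, j] <- sqrt(sv$d[j] * sigma) * up / n_up
          H[j, ] <- sqrt(sv$d[j] * sigma) * vp / n_vp
        }
      } else {
        sigma <- n_un * n_vn
        if (sigma > 0) {
          W[, j] <- sqrt(sv$d[j] * sigma) * un / n_un
          H[j, ] <- sqrt(sv$d[j] * sigma) * vn / n_vn
        }
      }
    }
  }
  avg <- mean(X)
  W[W <= 0] <- avg; H[H <= 0] <- avg
  list(W = W, H = H)
}

#' Consensus-based rank selection via the cophenetic correlation
#'
#' For every rank in `k_range`, runs `n_runs` randomly initialized
#' factorizations, co-clusters subjects by their dominant factor, and builds
#' the subject x subject consensus matrix (fraction of runs in which two
#' subjects share a dominant factor). Rank stability is scored by the
#' cophenetic correlation between the consensus dissimilarity and the
#' cophenetic distances of its average-linkage hierarchical clustering.
#' Ranks whose cophenetic value reaches `stability_threshold` are retained
#' (the most stable rank is always retained), and sets are later accumulated
#' across retained ranks.
#'
#' @param X nonnegative matrix or [feature_matrix()].
#' @param k_range integer vector of candidate ranks.
#' @param n_runs factorizations per rank (>= 2).
#' @param seed base seed; run r at rank k uses a seed derived from it (all
#'   seeds are returned).
#' @param stability_threshold cophenetic value at or above which a rank is
#'   retained (default 0.95).
#' @param max_iter,tol forwarded to [nmf_factorize()].
#' @return list: `ranks`, `cophenetic` (named by rank), `chosen` (retained
#'   ranks), `consensus` (list of matrices, named by rank), `seeds`.
#' @export
select_ranks <- function(X, k_range, n_runs = 10, seed = 1,
                         stability_threshold = 0.95,
                         max_iter = 200, tol = 1e-5) {
  if (inherits(X, "feature_matrix")) X <- X$values
  if (!length(k_range)) stop("k_range must be nonempty")
  if (n_runs < 2) stop("n_runs must be >= 2")
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(X)
  coph <- stats::setNames(numeric(length(k_range)), k_range)
  consensus <- stats::setNames(vector("list", length(k_range)), k_range)
  seeds <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    C <- matrix(0, n, n)
    run_seeds <- seed + 1000L * ki + seq_len(n_runs)
    seeds[[as.character(k)]] <- run_seeds
    for (r in seq_len(n_runs)) {
      fp <- nmf_factorize(X, k, seed = run_seeds[r], max_iter = max_iter,
                          tol = tol, init = "random")
      cl <- max.col(fp$W, ties.method = "first")
      C <- C + outer(cl, cl, "==")
    }
    C <- C / n_runs
    consensus[[ki]] <- C
    coph[ki] <- consensus_cophenetic(C)
  }
  chosen <- k_range[coph >= stability_threshold - 1e-12]
  if (!length(chosen)) chosen <- k_range[which.max(coph)]
  list(ranks = k_range, cophenetic = coph, chosen = chosen,
       consensus = consensus, seeds = seeds)
}

consensus_cophenetic <- function(C) {
  d <- stats::as.dist(1 - C)
  if (all(d == d[1])) {
    # degenerate: identical assignments in every run (or a single cluster)
    warning("degenerate consensus matrix; cophenetic reported as 1")
    return(1)
  }
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  suppressWarnings(cc <- stats::cor(d, cd))
  if (is.na(cc)) 1 else cc
}

#' Extract biclusters ("sets") from a factorization
#'
#' One candidate bicluster per factor: the subjects whose loading on the
#' factor passes the subject policy and the features passing the feature
#' policy. The default policy is relative-max: membership requires a loading
#' of at least `threshold` times the factor's maximum loading. Empty
#' candidates are dropped.
#'
#' The membership policy is configurable per axis:
#' * `"bimodal"` (default): the loadings are split into a low and a high
#'   group by two-means clustering; the high group is the set. This
#'   self-calibrates to each factor's loading scale. Degenerate (constant)
#'   loadings retain every index.
#' * `"relative_max"`: membership requires a loading of at least
#'   `threshold` times the factor's maximum loading.
#'
#' @param fp a `factor_pair` from [nmf_factorize()].
#' @param domain domain tag for the collection (determines the id prefix,
#'   e.g. `"character"` sets are `C_<rank>_<factor>`).
#' @param subject_policy,feature_policy `"bimodal"` or `"relative_max"`.
#' @param subject_threshold,feature_threshold relative-max thresholds in
#'   (0, 1] (used by the `"relative_max"` policy).
#' @param subject_ids,feature_ids optional id vectors (defaults `S<i>` /
#'   `F<j>`).
#' @return a `set_collection`.
#' @export
extract_biclusters <- function(fp, domain = "character",
                               subject_policy = c("bimodal", "relative_max"),
                               feature_policy = c("bimodal", "relative_max"),
                               subject_threshold = 0.5,
                               feature_threshold = 0.5,
                               subject_ids = NULL, feature_ids = NULL) {
  stopifnot(inherits(fp, "factor_pair"))
  subject_policy <- match.arg(subject_policy)
  feature_policy <- match.arg(feature_policy)
  n <- nrow(fp$W); p <- ncol(fp$H)
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(p))
  prefix <- toupper(substr(domain, 1, 1))
  pick <- function(x, policy, threshold) {
    if (max(x) == 0) return(integer(0))
    if (policy == "relative_max" || min(x) == max(x))
      return(which(x >= threshold * max(x) & x > 0))
    km <- stats::kmeans(x, centers = c(min(x), max(x)))
    which(km$cluster == which.max(km$centers))
  }
  sets <- list()
  for (j in seq_len(fp$k)) {
    w <- fp$W[, j]; h <- fp$H[j, ]
    subj <- unname(pick(w, subject_policy, subject_threshold))
    feat <- unname(pick(h, feature_policy, feature_threshold))
    if (!length(subj) || !length(feat)) next
    sets[[length(sets) + 1L]] <- list(
      id = sprintf("%s_%d_%d", prefix, fp$k, j),
      domain = domain,
      subjects = subj, subject_ids = subject_ids[subj],
      features = feat, feature_ids = feature_ids[feat],
      subject_weights = unname(w[subj]), feature_weights = unname(h[feat]),
      rank = fp$k, factor = j)
  }
  if (!length(sets))
    warning("threshold policy produced an empty set collection")
  set_collection(sets, cohort_size = n, domain = domain)
}

#' Construct a set collection
#'
#' @param biclusters list of bicluster records (id, domain, subjects,
#'   features, weights, rank, factor).
#' @param cohort_size number of subjects in the cohort the sets index into.
#' @param domain domain tag.
#' @param meta optional selection metadata (ranks used, cophenetic values).
#' @return object of class `set_collection`.
#' @export
set_collection <- function(biclusters, cohort_size, domain, meta = list()) {
  ids <- vapply(biclusters, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("bicluster ids must be unique")
  for (b in biclusters) {
    if (!length(b$subjects) || !length(b$features))
      stop("bicluster ", b$id, " has an empty axis")
    if (any(b$subjects > cohort_size))
      stop("bicluster ", b$id, " references subjects beyond the cohort")
  }
  structure(list(biclusters = biclusters,
                 cohort_size = as.integer(cohort_size),
                 domain = domain, meta = meta),
            class = "set_collection")
}

#' @export
print.set_collection <- function(x, ...) {
  cat(sprintf("set_collection [%s]: %d sets over %d subjects\n",
              x$domain, length(x$biclusters), x$cohort_size))
  invisible(x)
}

#' @export
length.set_collection <- function(x) length(x$biclusters)

set_ids <- function(sc) vapply(sc$biclusters, `[[`, character(1), "id")

#' Factorize a matrix across ranks and accumulate sets
#'
#' Convenience pipeline step: selects stable ranks on `X` by
#' [select_ranks()] (or uses every rank in `k_range` when
#' `rank_selection = "all"`), factorizes deterministically at each retained
#' rank, and accumulates the extracted biclusters into one collection.
#'
#' @param X [feature_matrix()] (or plain matrix).
#' @param domain domain tag; defaults to the matrix's own.
#' @param k_range candidate ranks.
#' @param n_runs consensus runs per rank.
#' @param seed integer seed.
#' @param rank_selection `"cophenetic"` (consensus selection) or `"all"`.
#' @param baseline `"median"` (subtract each feature's median and clip at
#'   0, so factors model above-typical exceedance — the default for scored
#'   phenotype/environment scales, whose shared baseline otherwise
#'   dominates the factors) or `"none"` (raw values — the default for
#'   genotype dosage, which is already a count above a zero baseline).
#'   `NULL` picks by domain.
#' @param subject_policy,feature_policy,subject_threshold,feature_threshold
#'   forwarded to [extract_biclusters()].
#' @param max_iter,tol forwarded to [nmf_factorize()].
#' @param stability_threshold forwarded to [select_ranks()].
#' @return a `set_collection` with selection metadata.
#' @export
derive_sets <- function(X, domain = NULL, k_range = 2:6, n_runs = 10,
                        seed = 1, rank_selection = c("cophenetic", "all"),
                        baseline = NULL,
                        subject_policy = "bimodal",
                        feature_policy = "bimodal",
                        subject_threshold = 0.5, feature_threshold = 0.5,
                        stability_threshold = 0.95,
                        max_iter = 200, tol = 1e-5) {
  rank_selection <- match.arg(rank_selection)
  if (inherits(X, "feature_matrix")) {
    if (is.null(domain)) domain <- X$domain
    sid <- subject_ids(X); fid <- feature_ids(X)
    Xv <- X$values
  } else {
    if (is.null(domain)) domain <- "character"
    Xv <- as.matrix(X)
    sid <- rownames(Xv); fid <- colnames(Xv)
  }
  if (is.null(baseline))
    baseline <- if (domain == "genotype") "none" else "median"
  baseline <- match.arg(baseline, c("median", "none"))
  if (baseline == "median") {
    med <- apply(Xv, 2, stats::median, na.rm = TRUE)
    Xv <- pmax(sweep(Xv, 2, med), 0)
  }
  k_range <- k_range[k_range <= min(dim(Xv))]
  if (!length(k_range)) stop("k_range has no feasible rank for this matrix")
  meta <- list(k_range = k_range, rank_selection = rank_selection,
               baseline = baseline, seed = seed)
  if (rank_selection == "cophenetic") {
    sel <- select_ranks(Xv, k_range, n_runs = n_runs, seed = seed,
                        stability_threshold = stability_threshold,
                        max_iter = max_iter, tol = tol)
    ranks <- sel$chosen
    meta$cophenetic <- sel$cophenetic
    meta$chosen <- sel$chosen
  } else {
    ranks <- k_range
  }
  sets <- list()
  for (k in ranks) {
    fp <- nmf_factorize(Xv, k, seed = seed, max_iter = max_iter, tol = tol,
                        init = "nndsvd")
    sc_k <- suppressWarnings(
      extract_biclusters(fp, domain = domain,
                         subject_policy = subject_policy,
                         feature_policy = feature_policy,
                         subject_threshold = subject_threshold,
                         feature_threshold = feature_threshold,
                         subject_ids = sid, feature_ids = fid))
    sets <- c(sets, sc_k$biclusters)
  }
  if (!length(sets))
    warning("no biclusters extracted at any retained rank")
  set_collection(sets, cohort_size = nrow(Xv), domain = domain, meta = meta)
}

#' Group sets into deep profiles
#'
#' Builds the set x feature centroid matrix (each set's feature weights,
#' normalized to unit sum, placed at its member features) and factorizes it
#' by NMF at rank `n_profiles`; each set is assigned to its maximal profile
#' factor.
#'
#' @param sc a `set_collection`.
#' @param n_profiles number of profiles (<= number of sets).
#' @param seed integer seed.
#' @param n_features width of the centroid matrix (defaults to the largest
#'   feature index seen).
#' @return list of class `profile_assignment`: `labels` (named integer
#'   vector, one per set), `centroids` (profile x feature matrix),
#'   `n_profiles`.
#' @export
cluster_profiles <- function(sc, n_profiles, seed = 1, n_features = NULL) {
  stopifnot(inherits(sc, "set_collection"))
  ns <- length(sc$biclusters)
  if (n_profiles > ns)
    stop(sprintf("n_profiles = %d exceeds the %d available sets",
                 n_profiles, ns))
  if (is.null(n_features))
    n_features <- max(vapply(sc$biclusters, function(b) max(b$features),
                             numeric(1)))
  Cm <- matrix(0, ns, n_features)
  for (i in seq_len(ns)) {
    b <- sc$biclusters[[i]]
    w <- b$feature_weights
    if (sum(w) > 0) w <- w / sum(w)
    Cm[i, b$features] <- w
  }
  fp <- nmf_factorize(Cm, n_profiles, seed = seed, init = "nndsvd")
  labels <- max.col(fp$W, ties.method = "first")
  names(labels) <- set_ids(sc)
  structure(list(labels = labels, centroids = fp$H,
                 n_profiles = as.integer(n_profiles)),
            class = "profile_assignment")
}

#' Jaccard similarity of two index sets
#' @param a,b integer (or character) vectors.
#' @return |intersection| / |union|.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Subject-axis recovery score of planted sets
#'
#' For every planted set of the requested domains, the best Jaccard
#' similarity (on the subject axis) over the recovered collection; returns
#' the per-set scores and their mean.
#'
#' @param truth a `synthetic_truth`.
#' @param sc a recovered `set_collection`.
#' @param domains planted domains to score (defaults to the collection's).
#' @return list: `scores` (named by planted set id), `mean`.
#' @export
recovery_score <- function(truth, sc, domains = sc$domain) {
  planted <- planted_sets_of(truth, domains)
  if (!length(planted)) stop("truth contains no planted sets for domain(s): ",
                             paste(domains, collapse = ", "))
  rec <- lapply(sc$biclusters, `[[`, "subjects")
  scores <- vapply(planted, function(p) {
    if (!length(rec)) return(0)
    max(vapply(rec, function(r) jaccard(p$subjects, r), numeric(1)))
  }, numeric(1))
  names(scores) <- vapply(planted, `[[`, character(1), "id")
  list(scores = scores, mean = mean(scores))
}
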