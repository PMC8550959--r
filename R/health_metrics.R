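#' Well-being and ill-being indices from TCI character scales
#'
#' Well-being: membership in the top decile of the product of the three
#' character scale totals, SD x CO x ST. Ill-being: membership in the
#' bottom decile of the sum SD + CO. Scale totals are the sums of each
#' scale's subscale columns. Decile cutpoints use the strict-quantile rule:
#' with distinct scores exactly `ceiling(0.1 * n)` subjects are flagged on
#' each index; scores tied at the cutpoint are not flagged (an all-ties
#' cohort flags nobody). The two flags are not mutually exclusive; their
#' overlap is reported, never silently resolved.
#'
#' @param phen a phenotype [feature_matrix()] whose scale metadata
#'   identifies SD, CO and ST subscales.
#' @param decile flagged fraction (default 0.1).
#' @return object of class `health_indices`: logical `well_being` and
#'   `ill_being` per subject, the underlying `product_score` and
#'   `sum_score`, the `cutpoints`, and `overlap_fraction` of the two flags.
#' @export
compute_indices <- function(phen, decile = 0.1) {
  stopifnot(inherits(phen, "feature_matrix"))
  if (is.null(phen$scales))
    stop("phenotype matrix lacks scale metadata (SD/CO/ST needed)")
  need <- c("SD", "CO", "ST")
  if (!all(need %in% phen$scales))
    stop("scale metadata must include SD, CO and ST subscales")
  totals <- scale_totals(phen, need)
  product_score <- totals[, "SD"] * totals[, "CO"] * totals[, "ST"]
  sum_score <- totals[, "SD"] + totals[, "CO"]
  n <- length(sum_score)
  m <- ceiling(decile * n)
  # strict-quantile cutpoints: the m-th order statistic from each end
  sorted_prod <- sort(product_score, na.last = NA)
  sorted_sum <- sort(sum_score, na.last = NA)
  hi_cut <- sorted_prod[length(sorted_prod) - m]
  lo_cut <- sorted_sum[m + 1]
  well <- !is.na(product_score) & product_score > hi_cut
  ill <- !is.na(sum_score) & sum_score < lo_cut
  structure(list(well_being = unname(well), ill_being = unname(ill),
                 product_score = unname(product_score),
                 sum_score = unname(sum_score),
                 cutpoints = c(well = hi_cut, ill = lo_cut),
                 decile = decile,
                 overlap_fraction = mean(well & ill)),
            class = "health_indices")
}

#' @export
print.health_indices <- function(x, ...) {
  cat(sprintf(
    "health_indices: %d subjects; %d well-being, %d ill-being flagged (overlap %.2f%%)\n",
    length(x$well_being), sum(x$well_being), sum(x$ill_being),
    100 * x$overlap_fraction))
  invisible(x)
}

#' Health probability of a set
#'
#' Fraction of the set's member subjects flagged well-being / ill-being.
#'
#' @param s a bicluster record (element of `set_collection$biclusters`) or
#'   an integer vector of subject indices.
#' @param h a `health_indices`.
#' @return named numeric vector `c(p_well, p_ill)`.
#' @export
set_health_probability <- function(s, h) {
  subjects <- if (is.list(s)) s$subjects else s
  if (!length(subjects)) stop("empty set has no health probability")
  c(p_well = mean(h$well_being[subjects]),
    p_ill = mean(h$ill_being[subjects]))
}

#' One-way ANOVA with Tukey HSD across networks
#'
#' Compares the networks on set-level health probabilities (or subject
#' flags), using the textbook sums-of-squares F statistic and Tukey's range
#' test via the studentized-range distribution.
#'
#' @param p a `network_partition` (with subject labels for
#'   `level = "subjects"`).
#' @param h a `health_indices`.
#' @param collections list of `set_collection`s providing the sets
#'   (required for `level = "sets"`).
#' @param outcome `"well"` or `"ill"`.
#' @param level `"sets"` (one observation per set: its health probability)
#'   or `"subjects"` (one 0/1 observation per assigned subject).
#' @return object of class `health_comparison`: per-network `n`, `mean`,
#'   `sd`; `F`, `df` (c(between, within)), `p_value`,
#'   `zero_within_variance` flag; `tukey` data.frame (pair, diff, q,
#'   p_adj, significant at 0.05).
#' @export
compare_networks <- function(p, h, collections = NULL,
                             outcome = c("well", "ill"),
                             level = c("sets", "subjects")) {
  outcome <- match.arg(outcome)
  level <- match.arg(level)
  stopifnot(inherits(p, "network_partition"))
  flag_name <- if (outcome == "well") "p_well" else "p_ill"
  if (level == "sets") {
    if (is.null(collections))
      stop("set-level comparison needs the set collections")
    if (inherits(collections, "set_collection"))
      collections <- list(collections)
    values <- numeric(0); groups <- integer(0)
    for (sc in collections) {
      labs <- collection_labels(p, sc)
      for (i in seq_along(sc$biclusters)) {
        if (is.na(labs[i])) next
        values <- c(values,
                    set_health_probability(sc$biclusters[[i]], h)[flag_name])
        groups <- c(groups, labs[i])
      }
    }
  } else {
    if (is.null(p$subject_labels))
      stop("subject-level comparison needs assigned subjects")
    keep <- p$subject_labels > 0
    flags <- if (outcome == "well") h$well_being else h$ill_being
    values <- as.numeric(flags[keep])
    groups <- p$subject_labels[keep]
  }
  anova_oneway(values, groups)
}

# textbook one-way ANOVA + Tukey HSD on a values/groups pair
anova_oneway <- function(values, groups) {
  tab <- table(groups)
  drop <- names(tab)[tab < 2]
  if (length(drop)) {
    warning("dropping group(s) with < 2 observations: ",
            paste(drop, collapse = ", "))
    keep <- !(groups %in% as.integer(drop))
    values <- values[keep]; groups <- groups[keep]
  }
  glev <- sort(unique(groups))
  k <- length(glev)
  if (k < 2) stop("need >= 2 groups with >= 2 observations each")
  n_i <- vapply(glev, function(g) sum(groups == g), numeric(1))
  m_i <- vapply(glev, function(g) mean(values[groups == g]), numeric(1))
  s_i <- vapply(glev, function(g) stats::sd(values[groups == g]), numeric(1))
  n <- length(values)
  grand <- mean(values)
  ss_between <- sum(n_i * (m_i - grand)^2)
  ss_within <- sum((values - m_i[match(groups, glev)])^2)
  df_b <- k - 1
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  zero_within <- ms_w == 0
  F_stat <- if (zero_within) {
    if (ss_between == 0) 0 else Inf
  } else ms_b / ms_w
  p_value <- if (is.infinite(F_stat)) 0 else
    stats::pf(F_stat, df_b, df_w, lower.tail = FALSE)
  pairs <- utils::combn(seq_len(k), 2)
  tukey <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    diff <- m_i[j] - m_i[i]
    se <- sqrt(ms_w / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- if (se == 0) { if (diff == 0) 0 else Inf } else abs(diff) / se
    p_adj <- if (is.infinite(q)) 0 else
      stats::ptukey(q, k, df_w, lower.tail = FALSE)
    data.frame(pair = sprintf("%d-%d", glev[j], glev[i]), diff = diff,
               q = q, p_adj = p_adj, significant = p_adj < 0.05,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = glev, n = n_i, mean = m_i, sd = s_i,
                 F = F_stat, df = c(between = df_b, within = df_w),
                 p_value = p_value, zero_within_variance = zero_within,
                 tukey = tukey),
            class = "health_comparison")
}

#' @export
print.health_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, df = (%d, %d), p = %.3g%s\n",
              x$F, x$df[1], x$df[2], x$p_value,
              if (x$zero_within_variance) " [zero within-group variance]"
              else ""))
  for (i in seq_along(x$groups))
    cat(sprintf("  network %d: n = %d, mean = %.4g +/- %.4g\n",
                x$groups[i], x$n[i], x$mean[i], x$sd[i]))
  invisible(x)
}

#' Ordered health-surface matrix of a relation graph
#'
#' Rows are source (character) sets and columns target (temperament) sets,
#' both ordered by average-linkage hierarchical clustering of their
#' pairwise shared-subject similarity (-log10 hypergeometric p, capped).
#' Each cell holding a significant relation carries the health probability
#' of the subjects in the two sets' intersection; cells without a relation
#' are NA (interpolation is a rendering concern and is not done here).
#'
#' @param g a `relation_graph` with significant relations.
#' @param h a `health_indices`.
#' @param outcome `"well"` or `"ill"`.
#' @param cap cap for the -log10 similarity (default 300).
#' @return list: `surface` (ordered matrix with NA for absent cells),
#'   `row_order`, `col_order` (set ids in plot order).
#' @export
health_surface <- function(g, h, outcome = c("well", "ill"), cap = 300) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(g, "relation_graph"))
  flag_name <- if (outcome == "well") "p_well" else "p_ill"
  rel <- significant_relations(g)
  if (!nrow(rel)) stop("graph has no significant relations")
  row_order <- cluster_order(g$source, cap)
  col_order <- cluster_order(g$target, cap)
  S <- matrix(NA_real_, length(row_order), length(col_order),
              dimnames = list(row_order, col_order))
  subj_a <- lapply(g$source$biclusters, `[[`, "subjects")
  names(subj_a) <- set_ids(g$source)
  subj_b <- lapply(g$target$biclusters, `[[`, "subjects")
  names(subj_b) <- set_ids(g$target)
  for (r in seq_len(nrow(rel))) {
    inter <- intersect(subj_a[[rel$source[r]]], subj_b[[rel$target[r]]])
    if (!length(inter)) next
    S[rel$source[r], rel$target[r]] <-
      set_health_probability(inter, h)[flag_name]
  }
  list(surface = S, row_order = row_order, col_order = col_order)
}

# order a collection's sets by average-linkage clustering of pairwise
# shared-subject -log10 hypergeometric p
cluster_order <- function(sc, cap = 300) {
  ids <- set_ids(sc)
  ns <- length(ids)
  if (ns == 1) return(ids)
  n <- sc$cohort_size
  sizes <- vapply(sc$biclusters, function(b) length(b$subjects), integer(1))
  ov <- as.matrix(Matrix::crossprod(membership_matrix(sc)))
  sim <- matrix(0, ns, ns)
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    p <- as.numeric(overlap_pvalue(ov[i, j], sizes[i], sizes[j], n))
    sim[i, j] <- sim[j, i] <- min(cap, -log10(max(p, 10^(-cap))))
  }
  d <- stats::as.dist(max(sim) - sim)
  hc <- stats::hclust(d, method = "average")
  ids[hc$order]
}
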