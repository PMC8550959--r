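#' Configuration for a synthetic genotype-phenotype-environment cohort
#'
#' Describes a cohort with planted biclusters organized into `n_networks`
#' near-disjoint networks: each network owns a block of subjects and, per
#' data domain, a pool of features on which its planted sets elevate values
#' above background. The defaults emulate a discovery cohort of ~2000
#' subjects assessed on 16 temperament and 13 character TCI subscales,
#' genotyped at 1000 SNPs, with 15 measured environmental variables.
#'
#' @param n_subjects cohort size.
#' @param n_temperament_subscales,n_character_subscales phenotype widths;
#'   the first 16 / 13 get standard TCI subscale labels (NS1-4, HA1-4,
#'   RD1-4, PS1-4; SD1-5, CO1-5, ST1-3).
#' @param n_snps,n_env_vars genotype / environment widths.
#' @param n_networks number of planted networks (default 3).
#' @param sets_per_domain_per_network named integer vector: planted sets per
#'   network for each domain.
#' @param disjointness in \[0,1\]: 1 means the planted feature pools of
#'   distinct networks share nothing; lower values allocate a shared slice
#'   of each pool that is common to all networks.
#' @param effect_size additive mean shift of planted cells, in units of the
#'   reference residual scale (1 point on phenotype subscales).
#' @param noise_sd residual standard deviation of the phenotype background.
#' @param missing_rate MCAR missingness fraction applied to every matrix.
#' @param maf_range background minor-allele-frequency interval, within
#'   (0, 0.5].
#' @param unassigned_fraction fraction of subjects left as pure background
#'   (in no network).
#' @param subject_fraction fraction of a network's subject block each
#'   planted set samples.
#' @param feature_fraction fraction of a network's feature pool each
#'   planted set samples.
#' @param snp_pool_size planted-SNP pool size per network.
#' @param structure_strength ancestry-confound magnitude: SD of the
#'   per-population logit shift of allele frequencies (0 = no structure).
#' @param seed integer seed controlling every random draw.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 2000,
                          n_temperament_subscales = 16,
                          n_character_subscales = 13,
                          n_snps = 1000,
                          n_env_vars = 15,
                          n_networks = 3,
                          sets_per_domain_per_network = c(temperament = 2,
                                                          character = 2,
                                                          genotype = 2,
                                                          environment = 2),
                          disjointness = 0.9,
                          effect_size = 2,
                          noise_sd = 1,
                          missing_rate = 0,
                          maf_range = c(0.05, 0.5),
                          unassigned_fraction = 0.05,
                          subject_fraction = 0.9,
                          feature_fraction = 0.8,
                          snp_pool_size = 40,
                          structure_strength = 0,
                          seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_temperament_subscales = as.integer(n_temperament_subscales),
              n_character_subscales = as.integer(n_character_subscales),
              n_snps = as.integer(n_snps),
              n_env_vars = as.integer(n_env_vars),
              n_networks = as.integer(n_networks),
              sets_per_domain_per_network =
                vapply(sets_per_domain_per_network, as.integer, integer(1)),
              disjointness = disjointness,
              effect_size = effect_size,
              noise_sd = noise_sd,
              missing_rate = missing_rate,
              maf_range = as.numeric(maf_range),
              unassigned_fraction = unassigned_fraction,
              subject_fraction = subject_fraction,
              feature_fraction = feature_fraction,
              snp_pool_size = as.integer(snp_pool_size),
              structure_strength = structure_strength,
              seed = as.integer(seed))
  counts <- c(cfg$n_subjects, cfg$n_temperament_subscales,
              cfg$n_character_subscales, cfg$n_snps, cfg$n_env_vars,
              cfg$n_networks, cfg$sets_per_domain_per_network,
              cfg$snp_pool_size)
  if (any(counts <= 0)) stop("all counts must be positive")
  fr <- c(cfg$disjointness, cfg$missing_rate, cfg$unassigned_fraction,
          cfg$subject_fraction, cfg$feature_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  req <- c("temperament", "character", "genotype", "environment")
  if (!all(req %in% names(cfg$sets_per_domain_per_network)))
    stop("sets_per_domain_per_network needs entries for: ",
         paste(req, collapse = ", "))
  class(cfg) <- "cohort_config"
  cfg
}

# Allocate per-network feature pools for one domain under the disjointness
# dial: each pool of size m has round((1-d)*m) features drawn from a slice
# shared by all networks and the remainder exclusive to the network.
allocate_pools <- function(n_features, pool_size, k, disjointness) {
  m <- min(pool_size, n_features %/% k + n_features %% k)
  m <- max(2L, min(m, pool_size))
  s <- round((1 - disjointness) * m)
  need <- s + k * (m - s)
  if (need > n_features)
    stop(sprintf(
      "infeasible sizing: %d planted features needed but only %d available",
      need, n_features))
  idx <- sample.int(n_features, need)
  shared <- if (s > 0) idx[seq_len(s)] else integer(0)
  rest <- idx[setdiff(seq_along(idx), seq_len(s))]
  lapply(seq_len(k), function(i) {
    excl <- rest[seq.int((i - 1) * (m - s) + 1, length.out = m - s)]
    sort(c(shared, excl))
  })
}

sample_subset <- function(x, fraction, min_size = 2L) {
  n <- max(min_size, round(fraction * length(x)))
  n <- min(n, length(x))
  sort(sample(x, n))
}

#' Generate a synthetic cohort with planted network structure
#'
#' Produces phenotype, genotype, and environment matrices over one cohort of
#' subjects, plus the ground truth of what was planted. Subjects are split
#' into `n_networks` disjoint blocks (plus an unassigned background
#' fraction); each network plants biclusters in every domain: subject
#' subsets of its block elevated on feature subsets of its pool.
#' Phenotype background is normal (mean 5, sd `noise_sd`) clipped at 0;
#' genotype background is Hardy-Weinberg at a uniform MAF in `maf_range`;
#' environment variables are ordinal 0-3. Environment sets are wired to
#' their network either directly (subjects from the phenotype block) or
#' indirectly (subjects from a mediating planted SNP set), and the wiring is
#' recorded in the truth.
#'
#' @param config a [cohort_config()].
#' @return list with elements `phenotype`, `genotype`, `environment`
#'   (each a [feature_matrix()]) and `truth` (a `synthetic_truth`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_networks
  spd <- config$sets_per_domain_per_network

  ## subject blocks ------------------------------------------------------
  n_unassigned <- round(config$unassigned_fraction * n)
  perm <- sample.int(n)
  assigned <- perm[seq_len(n - n_unassigned)]
  blocks <- split(assigned, rep_len(seq_len(k), length(assigned)))
  blocks <- lapply(blocks, sort)
  subject_labels <- integer(n)
  for (i in seq_len(k)) subject_labels[blocks[[i]]] <- i

  ## feature pools -------------------------------------------------------
  nt <- config$n_temperament_subscales
  nc <- config$n_character_subscales
  pools <- list(
    temperament = allocate_pools(nt, nt %/% k, k, config$disjointness),
    character   = allocate_pools(nc, nc %/% k, k, config$disjointness),
    genotype    = allocate_pools(config$n_snps, config$snp_pool_size, k,
                                 config$disjointness),
    environment = allocate_pools(config$n_env_vars, config$n_env_vars %/% k,
                                 k, config$disjointness))

  ## plant sets ----------------------------------------------------------
  planted <- list()
  for (net in seq_len(k)) {
    for (dom in c("temperament", "character", "genotype")) {
      for (j in seq_len(spd[[dom]])) {
        planted[[length(planted) + 1L]] <- list(
          id = sprintf("%s_net%d_%d", toupper(substr(dom, 1, 1)), net, j),
          domain = dom, network = net,
          subjects = sample_subset(blocks[[net]], config$subject_fraction),
          features = sample_subset(pools[[dom]][[net]],
                                   config$feature_fraction),
          wiring = NA_character_, mediator = NA_character_)
      }
    }
    snp_ids <- vapply(planted, function(s)
      if (s$domain == "genotype" && s$network == net) s$id else NA_character_,
      character(1))
    snp_ids <- snp_ids[!is.na(snp_ids)]
    for (j in seq_len(spd[["environment"]])) {
      wiring <- if (j %% 2L == 1L) "direct" else "indirect"
      if (wiring == "direct") {
        subj_pool <- blocks[[net]]
        mediator <- NA_character_
      } else {
        mediator <- snp_ids[1L + (j %/% 2L - 1L) %% length(snp_ids)]
        med <- Filter(function(s) s$id == mediator, planted)[[1]]
        subj_pool <- med$subjects
      }
      planted[[length(planted) + 1L]] <- list(
        id = sprintf("E_net%d_%d", net, j),
        domain = "environment", network = net,
        subjects = sample_subset(subj_pool, config$subject_fraction),
        features = sample_subset(pools[["environment"]][[net]],
                                 config$feature_fraction),
        wiring = wiring, mediator = mediator)
    }
  }

  materialize_cohort(config, planted, subject_labels)
}

# Draw background matrices, apply planted elevations and missingness.
# Continues the active RNG stream; callers seed it.
materialize_cohort <- function(config, planted, subject_labels) {
  n <- config$n_subjects
  nt <- config$n_temperament_subscales
  nc <- config$n_character_subscales

  tlab <- default_temperament_labels(nt)
  clab <- default_character_labels(nc)
  phen <- matrix(pmax(0, stats::rnorm(n * (nt + nc), mean = 5,
                                      sd = config$noise_sd)),
                 nrow = n, dimnames = list(paste0("S", seq_len(n)),
                                           c(tlab, clab)))

  maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  pop <- rep(1L, n)
  maf_mat <- matrix(maf, nrow = n, ncol = config$n_snps, byrow = TRUE)
  if (config$structure_strength > 0) {
    pop <- sample.int(3L, n, replace = TRUE)
    shift <- matrix(stats::rnorm(3 * config$n_snps, 0,
                                 config$structure_strength),
                    nrow = 3)
    maf_mat <- stats::plogis(stats::qlogis(maf_mat) + shift[pop, ])
  }
  gen <- matrix(stats::rbinom(n * config$n_snps, 2, maf_mat), nrow = n,
                dimnames = list(paste0("S", seq_len(n)),
                                paste0("rs", seq_len(config$n_snps))))

  env <- matrix(stats::rbinom(n * config$n_env_vars, 3, 0.3), nrow = n,
                dimnames = list(paste0("S", seq_len(n)),
                                paste0("ENV", seq_len(config$n_env_vars))))

  ## apply planted elevations (once per cell, via union masks) -----------
  masks <- list(
    temperament = matrix(FALSE, n, nt), character = matrix(FALSE, n, nc),
    genotype = matrix(FALSE, n, config$n_snps),
    environment = matrix(FALSE, n, config$n_env_vars))
  for (s in planted) masks[[s$domain]][s$subjects, s$features] <- TRUE

  phen[, seq_len(nt)][masks$temperament] <-
    phen[, seq_len(nt)][masks$temperament] + config$effect_size
  phen[, nt + seq_len(nc)][masks$character] <-
    phen[, nt + seq_len(nc)][masks$character] + config$effect_size

  mg <- masks$genotype
  if (any(mg)) {
    q_high <- pmin(0.95, maf_mat[mg] + 0.2 * config$effect_size)
    gen[mg] <- stats::rbinom(sum(mg), 2, q_high)
  }
  me <- masks$environment
  if (any(me)) {
    p_high <- min(0.9, 0.3 + 0.15 * config$effect_size)
    env[me] <- stats::rbinom(sum(me), 3, p_high)
  }

  ## MCAR missingness ----------------------------------------------------
  if (config$missing_rate > 0) {
    drop_cells <- function(m) {
      m[stats::runif(length(m)) < config$missing_rate] <- NA
      m
    }
    phen <- drop_cells(phen); gen <- drop_cells(gen); env <- drop_cells(env)
  }

  truth <- structure(list(planted_sets = planted,
                          subject_labels = subject_labels,
                          populations = pop,
                          config = unclass(config)),
                     class = "synthetic_truth")
  list(phenotype = feature_matrix(phen, "phenotype",
                                  scales_from_labels(c(tlab, clab))),
       genotype = feature_matrix(gen, "genotype"),
       environment = feature_matrix(env, "environment"),
       truth = truth)
}

#' Generate a twin cohort from an existing truth
#'
#' Re-draws a cohort with the SAME planted feature structure (the same
#' feature subsets, network wiring, and mediators as `truth`) but fresh
#' subjects, subject blocks and background noise — the situation of an
#' independent replication sample measured on the same instruments and
#' variants. Feature ids are shared with the original cohort, so
#' cross-cohort set matching by features is meaningful; subjects are not
#' comparable.
#'
#' @param truth a `synthetic_truth` from [generate_cohort()].
#' @param seed integer seed for the new cohort's randomness.
#' @param n_subjects optional new cohort size (default: same as template).
#' @return same structure as [generate_cohort()].
#' @export
generate_twin_cohort <- function(truth, seed, n_subjects = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- do.call(cohort_config, truth$config)
  config$seed <- as.integer(seed)
  if (!is.null(n_subjects)) config$n_subjects <- as.integer(n_subjects)
  set.seed(config$seed)
  n <- config$n_subjects
  k <- config$n_networks
  n_unassigned <- round(config$unassigned_fraction * n)
  perm <- sample.int(n)
  assigned <- perm[seq_len(n - n_unassigned)]
  blocks <- split(assigned, rep_len(seq_len(k), length(assigned)))
  blocks <- lapply(blocks, sort)
  subject_labels <- integer(n)
  for (i in seq_len(k)) subject_labels[blocks[[i]]] <- i

  planted <- list()
  new_subjects_of <- list()   # id -> resampled subjects (mediator lookup)
  for (tmpl in truth$planted_sets) {
    subj_pool <- if (!is.na(tmpl$wiring) && tmpl$wiring == "indirect")
      new_subjects_of[[tmpl$mediator]] else blocks[[tmpl$network]]
    s <- tmpl
    s$subjects <- sample_subset(subj_pool, config$subject_fraction)
    new_subjects_of[[s$id]] <- s$subjects
    planted[[length(planted) + 1L]] <- s
  }
  materialize_cohort(config, planted, subject_labels)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d planted sets, %d networks, %d subjects (%.1f%% unassigned)\n",
              length(x$planted_sets), x$config$n_networks,
              length(x$subject_labels),
              100 * mean(x$subject_labels == 0)))
  invisible(x)
}

planted_sets_of <- function(truth, domain = NULL) {
  sets <- truth$planted_sets
  if (!is.null(domain)) sets <- Filter(function(s) s$domain %in% domain, sets)
  sets
}

#' Write / read the planted ground truth
#'
#' Lossless round trip through a documented JSON schema: top-level keys
#' `planted_sets` (array of objects with id, domain, network, subjects,
#' features, wiring, mediator), `subject_labels`, `populations`, `config`.
#'
#' @param truth a `synthetic_truth`.
#' @param path file path.
#' @return `read_truth` returns the reconstructed `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  obj <- unclass(truth)
  # named vectors serialize as JSON objects only as lists
  obj$config$sets_per_domain_per_network <-
    as.list(obj$config$sets_per_domain_per_network)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE),
    error = function(e) stop("malformed truth file '", path, "': ",
                             conditionMessage(e)))
  for (key in c("planted_sets", "subject_labels", "config"))
    if (is.null(obj[[key]]))
      stop("malformed truth file '", path, "': missing key '", key, "'")
  obj$planted_sets <- lapply(obj$planted_sets, function(s) {
    s$subjects <- as.integer(s$subjects)
    s$features <- as.integer(s$features)
    s$network <- as.integer(s$network)
    if (is.null(s$wiring)) s$wiring <- NA_character_
    if (is.null(s$mediator)) s$mediator <- NA_character_
    s[c("id", "domain", "network", "subjects", "features",
        "wiring", "mediator")]
  })
  obj$subject_labels <- as.integer(obj$subject_labels)
  obj$populations <- as.integer(obj$populations)
  cfg <- obj$config
  int_fields <- c("n_subjects", "n_temperament_subscales",
                  "n_character_subscales", "n_snps", "n_env_vars",
                  "n_networks", "snp_pool_size", "seed")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$sets_per_domain_per_network <-
    vapply(cfg$sets_per_domain_per_network, as.integer, integer(1))
  cfg$maf_range <- as.numeric(cfg$maf_range)
  obj$config <- cfg
  structure(obj[c("planted_sets", "subject_labels", "populations", "config")],
            class = "synthetic_truth")
}
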