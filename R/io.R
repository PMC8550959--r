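# Readers and writers. Canonical tabular dialect: tab-separated, header
# row, UTF-8, "NA" for missing. Matrices carry the subject id in the first
# column ("subject_id"), feature ids in the header.

#' Write / read a feature matrix as TSV
#'
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @param domain,schema for the reader: the domain tag and, for phenotype
#'   data, a named character vector mapping every column to its scale
#'   (defaults to inferring `NS1 -> NS` style labels).
#' @return `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(subject_id = subject_ids(fm), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, domain = "phenotype", schema = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (!ncol(df) >= 2) stop("expected a subject_id column plus features in ",
                           path)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals) & vals != "", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d, column '%s' in %s",
                 bad[1, 1], colnames(vals)[bad[1, 2]], path))
  if (domain %in% c("phenotype", "temperament", "character")) {
    if (is.null(schema)) schema <- scales_from_labels(colnames(num))
    extra <- setdiff(colnames(num), names(schema))
    if (length(extra))
      stop("column(s) not in schema: ", paste(extra, collapse = ", "))
    known <- c("NS", "HA", "RD", "PS", "SD", "CO", "ST")
    bad_scale <- setdiff(unique(schema[colnames(num)]), known)
    if (length(bad_scale))
      stop("schema maps column(s) to unknown scale(s): ",
           paste(bad_scale, collapse = ", "))
    return(feature_matrix(num, domain, schema[colnames(num)]))
  }
  feature_matrix(num, domain)
}

#' Load a phenotype TSV with scale schema validation
#'
#' @param path TSV file (subject_id column + one column per subscale).
#' @param schema named character vector: column -> scale label; defaults to
#'   inferring the scale from the column name (`NS1` -> `NS`).
#' @return a phenotype [feature_matrix()].
#' @export
load_phenotypes <- function(path, schema = NULL) {
  read_feature_matrix(path, domain = "phenotype", schema = schema)
}

#' Load a genotype matrix (PLINK ped/map, VCF, or dosage TSV)
#'
#' Dispatches on the file extension: `.ped` (with its `.map` sibling),
#' `.vcf`/`.vcf.gz`, else dosage TSV. Dosage counts the alternate allele as
#' declared in the source file; no strand flipping is attempted.
#' Multiallelic VCF records are skipped with a logged count.
#'
#' @param path input file.
#' @return a genotype [feature_matrix()] (dosage 0/1/2, NA missing).
#' @export
load_genotypes <- function(path) {
  if (grepl("\\.ped$", path)) return(read_plink_pedmap(path))
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_vcf_dosage(path))
  read_feature_matrix(path, domain = "genotype")
}

#' Write a genotype matrix as a PLINK ped/map pair
#'
#' Text PLINK format with biallelic A (reference) / B (alternate) coding:
#' dosage is the B-allele count; missing genotypes are written `0 0`.
#'
#' @param fm a genotype [feature_matrix()].
#' @param prefix output prefix (writes `<prefix>.ped` and `<prefix>.map`).
#' @return invisible prefix.
#' @export
write_plink <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"), fm$domain == "genotype")
  X <- fm$values
  map <- data.frame(chr = 1L, id = colnames(X), cm = 0L,
                    pos = seq_len(ncol(X)))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  allele_txt <- function(d) {
    if (is.na(d)) return("0\t0")
    c("A\tA", "A\tB", "B\tB")[d + 1]
  }
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(X))) {
    geno <- vapply(X[i, ], allele_txt, character(1))
    cat(paste(c(rownames(X)[i], rownames(X)[i], 0, 0, 0, -9, geno),
              collapse = "\t"), "\n", sep = "", file = con)
  }
  invisible(prefix)
}

read_plink_pedmap <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (!file.exists(map_path))
    stop("missing .map sibling for ", ped_path)
  map <- utils::read.table(map_path, stringsAsFactors = FALSE)
  snp_ids <- map[[2]]
  ped <- utils::read.table(ped_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  n_allele_cols <- ncol(ped) - 6
  if (n_allele_cols != 2 * length(snp_ids))
    stop(sprintf(
      "ped/map length mismatch: %d allele columns but %d map variants",
      n_allele_cols, length(snp_ids)))
  a1 <- as.matrix(ped[, 6 + 2 * seq_along(snp_ids) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_along(snp_ids), drop = FALSE])
  dosage <- (a1 == "B") + (a2 == "B")
  dosage[a1 == "0" | a2 == "0"] <- NA
  dimnames(dosage) <- list(ped[[2]], snp_ids)
  feature_matrix(dosage, "genotype")
}

read_vcf_dosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dosage <- matrix(vapply(as.vector(gt), count_alt, numeric(1)),
                   nrow = nrow(gt), dimnames = dimnames(gt))
  feature_matrix(t(dosage), "genotype")   # subjects x SNPs
}

#' Serialize a set collection
#'
#' TSV: one row per set (id, domain, rank, factor, subject ids ;-joined,
#' feature ids ;-joined). JSON keeps full fidelity including weights.
#'
#' @param sc a `set_collection`.
#' @param path output path (`.json` for JSON, else TSV).
#' @return `read_set_collection` reconstructs the collection (from JSON).
#' @export
write_set_collection <- function(sc, path) {
  stopifnot(inherits(sc, "set_collection"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(domain = sc$domain, cohort_size = sc$cohort_size,
           meta = sc$meta, biclusters = sc$biclusters),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  } else {
    df <- data.frame(
      id = set_ids(sc), domain = sc$domain,
      rank = vapply(sc$biclusters, function(b) as.integer(b$rank),
                    integer(1)),
      factor = vapply(sc$biclusters, function(b) as.integer(b$factor),
                      integer(1)),
      subjects = vapply(sc$biclusters, function(b)
        paste(b$subject_ids, collapse = ";"), character(1)),
      features = vapply(sc$biclusters, function(b)
        paste(b$feature_ids, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_set_collection
#' @param path JSON path written by `write_set_collection`.
#' @export
read_set_collection <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  bics <- lapply(obj$biclusters, function(b) {
    b$subjects <- as.integer(b$subjects)
    b$features <- as.integer(b$features)
    b$subject_ids <- as.character(b$subject_ids)
    b$feature_ids <- as.character(b$feature_ids)
    b$subject_weights <- as.numeric(b$subject_weights)
    b$feature_weights <- as.numeric(b$feature_weights)
    b$rank <- as.integer(b$rank)
    b$factor <- as.integer(b$factor)
    b
  })
  set_collection(bics, cohort_size = as.integer(obj$cohort_size),
                 domain = obj$domain,
                 meta = if (is.null(obj$meta)) list() else obj$meta)
}

#' Serialize a relation graph's edge list as TSV
#'
#' @param g a `relation_graph`.
#' @param path output TSV.
#' @export
write_relation_graph <- function(g, path) {
  stopifnot(inherits(g, "relation_graph"))
  utils::write.table(g$relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a network partition as JSON
#'
#' Set labels, subject labels (0 = unassigned), counts, and the
#' well-being ordering record.
#'
#' @param p a `network_partition`.
#' @param path output JSON.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "network_partition"))
  jsonlite::write_json(
    list(k = p$k,
         source_labels = as.list(p$source_labels),
         target_labels = as.list(p$target_labels),
         subject_labels = p$subject_labels,
         unassigned_fraction = p$unassigned_fraction,
         network_sizes = if (is.null(p$subject_labels)) NULL else
           as.integer(table(factor(p$subject_labels,
                                   levels = seq_len(p$k)))),
         network_order = p$network_order, seed = p$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly; unknown keys in the file are rejected by
#' [pipeline_config()].
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a validated [pipeline_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

#' Write a pipeline result directory
#'
#' Serializes every component of a `pipeline_result` (collections as JSON,
#' relations and reports as TSV, partition as JSON) plus a manifest
#' (config echo, seed, package version). File contents are deterministic
#' for a fixed result.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_pipeline_result <- function(res, dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }
  write_set_collection(res$temperament_sets,
                       put(file.path(dir, "temperament_sets.json")))
  write_set_collection(res$character_sets,
                       put(file.path(dir, "character_sets.json")))
  write_relation_graph(res$phen_graph,
                       put(file.path(dir, "phenotype_relations.tsv")))
  write_partition(res$partition, put(file.path(dir, "partition.json")))
  hdf <- data.frame(subject = seq_along(res$health$well_being),
                    product_score = res$health$product_score,
                    sum_score = res$health$sum_score,
                    well_being = res$health$well_being,
                    ill_being = res$health$ill_being)
  utils::write.table(hdf, put(file.path(dir, "health_indices.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$snp_sets))
    write_set_collection(res$snp_sets, put(file.path(dir, "snp_sets.json")))
  if (!is.null(res$env_sets))
    write_set_collection(res$env_sets, put(file.path(dir, "env_sets.json")))
  if (!is.null(res$snp_assoc))
    utils::write.table(res$snp_assoc$tests,
                       put(file.path(dir, "snp_network_assoc.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$env_report))
    utils::write.table(res$env_report$report,
                       put(file.path(dir, "env_associations.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = unclass(res$config),
    seed = res$config$seed,
    package_version = as.character(utils::packageVersion("phenonet")),
    files = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "manifest.json")))
}
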