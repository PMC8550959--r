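#' Subjects-by-features matrix with domain metadata
#'
#' The universal input container of the pipeline: a numeric matrix of subjects
#' (rows) by features (columns) tagged with the domain it measures
#' (temperament or character subscales, SNP dosages, or environmental
#' variables) and, for phenotype domains, the scale each subscale belongs to
#' (NS/HA/RD/PS for temperament, SD/CO/ST for character).
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#'   Dimnames are used as subject and feature ids; defaults are generated
#'   when absent.
#' @param domain one of `"temperament"`, `"character"`, `"phenotype"`,
#'   `"genotype"`, `"environment"`.
#' @param scales optional named character vector mapping every feature id to
#'   a scale label (e.g. `c(NS1 = "NS", ...)`). Required by the health
#'   indices; ignored for non-phenotype domains.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values,
                           domain = c("temperament", "character", "phenotype",
                                      "genotype", "environment"),
                           scales = NULL) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  if (domain == "genotype") {
    ok <- values[!is.na(values)]
    if (length(ok) && !all(ok %in% c(0, 1, 2)))
      stop("genotype values must be dosages in {0, 1, 2} or NA")
  }
  if (!is.null(scales)) {
    missing_feat <- setdiff(colnames(values), names(scales))
    if (length(missing_feat))
      stop("scales metadata missing for features: ",
           paste(missing_feat, collapse = ", "))
    scales <- scales[colnames(values)]
  }
  structure(list(values = values, domain = domain, scales = scales),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d subjects x %d features, %d missing\n",
              x$domain, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

subject_ids <- function(fm) rownames(fm$values)
feature_ids <- function(fm) colnames(fm$values)

#' Split a combined phenotype matrix into temperament and character matrices
#'
#' Uses the scale metadata: NS/HA/RD/PS subscales go to the temperament
#' matrix, SD/CO/ST to the character matrix.
#'
#' @param fm a `feature_matrix` with domain `"phenotype"` and scale metadata.
#' @return list with elements `temperament` and `character`.
#' @export
split_phenotype <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$scales))
    stop("phenotype matrix lacks scale metadata; cannot split")
  temp_scales <- c("NS", "HA", "RD", "PS")
  char_scales <- c("SD", "CO", "ST")
  bad <- setdiff(unique(fm$scales), c(temp_scales, char_scales))
  if (length(bad))
    stop("unknown scale labels: ", paste(bad, collapse = ", "))
  tcols <- names(fm$scales)[fm$scales %in% temp_scales]
  ccols <- names(fm$scales)[fm$scales %in% char_scales]
  list(
    temperament = feature_matrix(fm$values[, tcols, drop = FALSE],
                                 "temperament", fm$scales[tcols]),
    character   = feature_matrix(fm$values[, ccols, drop = FALSE],
                                 "character", fm$scales[ccols])
  )
}

#' Scale totals of a phenotype matrix
#'
#' Sums the subscale columns of each named scale (TCI convention: a scale
#' total is the sum of its subscales). Missing subscale cells propagate NA.
#'
#' @param fm a `feature_matrix` carrying scale metadata.
#' @param scale_names character vector of scale labels to total.
#' @return numeric matrix, subjects x scales.
#' @export
scale_totals <- function(fm, scale_names = unique(fm$scales)) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(fm$scales))
    stop("feature_matrix lacks scale metadata")
  out <- sapply(scale_names, function(sc) {
    cols <- names(fm$scales)[fm$scales == sc]
    if (!length(cols)) stop("no subscales found for scale ", sc)
    rowSums(fm$values[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(fm$values),
                dimnames = list(subject_ids(fm), scale_names))
  out
}

# default TCI subscale labels used by the generator and the loaders
default_temperament_labels <- function(n = 16) {
  full <- paste0(rep(c("NS", "HA", "RD", "PS"), each = 4), rep(1:4, 4))
  if (n <= 16) full[seq_len(n)] else paste0("T", seq_len(n))
}

default_character_labels <- function(n = 13) {
  full <- c(paste0("SD", 1:5), paste0("CO", 1:5), paste0("ST", 1:3))
  if (n <= 13) full[seq_len(n)] else paste0("C", seq_len(n))
}

scales_from_labels <- function(labels) {
  sc <- sub("[0-9]+$", "", labels)
  names(sc) <- labels
  sc
}
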