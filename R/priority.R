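## Priority scoring. For each function type independently, every specific
## function in the disease's protein set gets the count mu of dataset
## proteins carrying it; a protein's raw score for that type is the sum of
## the counts of its own functions (the dot product of its binary presence
## profile rho with mu, computed by dictionary lookup rather than by
## materializing the arrays). Raw scores are normalized by eta * beta and
## averaged across types.

.datasetAnnotations <- function(dataset, ann) {
  df <- annotations(ann)
  df[df$protein_id %in% datasetProteins(dataset), , drop = FALSE]
}

#' Per-function protein counts within a disease dataset
#'
#' For each included function type, counts how many of the dataset's
#' proteins carry each specific function (the frequency vector mu), and the
#' number `a` of distinct functions of that type represented in the dataset.
#' Functions of proteins outside the dataset are ignored.
#'
#' @param dataset a [ProteinDiseaseDataset-class].
#' @param ann an [AnnotationTable-class] covering (at least) the dataset's
#'   proteins.
#' @param catalog optional [FunctionTypeCatalog-class]; defaults to the
#'   annotation table's own.
#' @return list with elements `p` (dataset size) and `byType`, a named list
#'   with, per included type, `mu` (named integer vector) and `a`.
#' @examples
#' cat3 <- functionTypeCatalog("uniprot_keyword")
#' ann <- annotationTable(data.frame(
#'   protein_id = c("A", "A", "B", "C"),
#'   function_type = "uniprot_keyword",
#'   function_id = c("f1", "f2", "f1", "f3")), cat3)
#' ds <- proteinDiseaseDataset("DOID:1", c("A", "B", "C"))
#' buildFrequencyIndex(ds, ann)$byType$uniprot_keyword$mu
#' @export
buildFrequencyIndex <- function(dataset, ann, catalog = NULL) {
  if (is.null(catalog)) catalog <- ann@catalog
  df <- .datasetAnnotations(dataset, ann)
  types <- includedTypes(catalog)
  byType <- lapply(types, function(ty) {
    sub <- df[df$function_type == ty, , drop = FALSE]
    if (!nrow(sub)) return(list(mu = integer(), a = 0L))
    counts <- table(sub$function_id)
    mu <- as.integer(counts)
    names(mu) <- names(counts)
    list(mu = mu, a = length(mu))
  })
  names(byType) <- types
  list(p = nProteins(dataset), byType = byType)
}

#' Raw priority score of one protein for one function type
#'
#' The sum, over the protein's functions of the given type, of the number of
#' dataset proteins carrying each function -- numerically the dot product of
#' the protein's binary presence profile with the dataset's function
#' frequency vector.
#'
#' @param proteinId protein accession; must belong to the dataset the index
#'   was built from.
#' @param index result of [buildFrequencyIndex()].
#' @param dataset the [ProteinDiseaseDataset-class] the index was built from.
#' @param ann the [AnnotationTable-class].
#' @param type a function type name present in the index.
#' @return a non-negative integer.
#' @export
rawPriority <- function(proteinId, index, dataset, ann, type) {
  if (!proteinId %in% datasetProteins(dataset))
    stop("protein ", proteinId, " is not in dataset ", diseaseId(dataset))
  if (!type %in% names(index$byType))
    stop("type ", type, " not in frequency index")
  df <- annotations(ann)
  funs <- df$function_id[df$protein_id == proteinId &
                           df$function_type == type]
  mu <- index$byType[[type]]$mu
  as.integer(sum(mu[funs]))
}

#' Normalization factors per function type
#'
#' For each included type: `eta = sqrt(p^2 + a^2)` (the sizes of the protein
#' set and of the type's function vocabulary in the dataset, combined in
#' quadrature, which puts scores from differently sized diseases on a
#' comparable scale) and `beta`, the mean number of functions of that type
#' per dataset protein (unannotated proteins count 0). A type absent from
#' the dataset has `a = 0`, `eta = p`, `beta = 0` and is unusable for
#' scoring.
#'
#' @inheritParams buildFrequencyIndex
#' @return data.frame with columns `function_type`, `a`, `eta`, `beta`.
#' @export
normalizationFactors <- function(dataset, ann, catalog = NULL) {
  if (is.null(catalog)) catalog <- ann@catalog
  idx <- buildFrequencyIndex(dataset, ann, catalog)
  p <- idx$p
  types <- names(idx$byType)
  a <- vapply(idx$byType, function(t) t$a, integer(1))
  tot <- vapply(idx$byType, function(t) sum(t$mu), numeric(1))
  data.frame(function_type = types, a = unname(a),
             eta = sqrt(p^2 + unname(a)^2), beta = unname(tot) / p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Normalize a raw priority score
#'
#' @param raw non-negative raw score.
#' @param eta,beta normalization factors; `beta` must be positive (a type
#'   with `beta == 0` carries no information for this dataset and must be
#'   excluded by the caller rather than scored).
#' @return `raw / (eta * beta)`.
#' @export
normalizedPriority <- function(raw, eta, beta) {
  if (any(beta <= 0))
    stop("beta must be positive; a type with beta == 0 is unusable")
  raw / (eta * beta)
}

#' Final priority scores for every protein of a dataset
#'
#' Computes per-type raw and normalized scores for every protein in the
#' dataset and averages the normalized scores over the usable included
#' types (those with `beta > 0`; types with no annotations in the dataset
#' drop out of the mean rather than contributing zeros). Unannotated
#' proteins score 0.
#'
#' @inheritParams buildFrequencyIndex
#' @return data.frame with one row per dataset protein: `disease_id`,
#'   `protein_id`, `priority`, `n_types_used`; the per-type raw and
#'   normalized score matrices are attached as attributes `raw` and `norm`.
#' @export
finalPriority <- function(dataset, ann, catalog = NULL) {
  if (is.null(catalog)) catalog <- ann@catalog
  proteins <- datasetProteins(dataset)
  p <- length(proteins)
  df <- .datasetAnnotations(dataset, ann)
  types <- includedTypes(catalog)
  raw <- matrix(0L, nrow = p, ncol = length(types),
                dimnames = list(proteins, types))
  eta <- numeric(length(types))
  beta <- numeric(length(types))
  for (k in seq_along(types)) {
    sub <- df[df$function_type == types[k], , drop = FALSE]
    a <- length(unique(sub$function_id))
    eta[k] <- sqrt(p^2 + a^2)
    beta[k] <- nrow(sub) / p
    if (!nrow(sub)) next
    counts <- table(sub$function_id)
    mu <- as.integer(counts)[match(sub$function_id, names(counts))]
    r <- rowsum(mu, group = sub$protein_id)
    raw[rownames(r), k] <- as.integer(r[, 1L])
  }
  usable <- beta > 0
  if (!any(usable)) {
    warning("dataset ", diseaseId(dataset),
            ": no usable function types; all priorities set to 0")
    final <- rep(0, p)
    norm <- matrix(NA_real_, p, 0)
  } else {
    norm <- sweep(raw[, usable, drop = FALSE], 2L,
                  (eta * beta)[usable], `/`)
    final <- rowMeans(norm)
  }
  out <- data.frame(disease_id = diseaseId(dataset), protein_id = proteins,
                    priority = unname(final),
                    n_types_used = sum(usable),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "raw") <- raw
  attr(out, "norm") <- norm
  out
}

#' Score every dataset of a collection
#'
#' @param datasets list of [ProteinDiseaseDataset-class].
#' @param ann an [AnnotationTable-class].
#' @param catalog optional [FunctionTypeCatalog-class].
#' @return data.frame stacking the [finalPriority()] rows of all datasets.
#' @export
scoreDiseases <- function(datasets, ann, catalog = NULL) {
  if (!length(datasets))
    return(data.frame(disease_id = character(), protein_id = character(),
                      priority = numeric(), n_types_used = integer(),
                      stringsAsFactors = FALSE))
  res <- lapply(datasets, finalPriority, ann = ann, catalog = catalog)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
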