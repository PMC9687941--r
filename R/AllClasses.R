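#' @import methods
NULL

## Nine annotation vocabularies scored independently before averaging.
.DEFAULT_TYPES <- c(
  "uniprot_keyword", "go_molecular_function", "go_biological_process",
  "go_cellular_component", "ec_number", "interpro", "superfamily",
  "chebi", "residue_feature"
)

## SUPERFAMILY and ChEBI alone do not discriminate known targets (their
## single-type AUCs are not above 0.5), so they are excluded by default.
.DEFAULT_EXCLUDED <- c("superfamily", "chebi")

#' Catalog of annotation (function) types
#'
#' An ordered list of annotation vocabularies ("function types") together
#' with a flag saying whether each participates in the priority score. The
#' default catalog holds the nine standard vocabularies: UniProt keywords,
#' the three Gene Ontology namespaces, EC numbers, InterPro, SUPERFAMILY,
#' ChEBI small-molecule interactions, and UniProt residue features.
#'
#' @slot typeNames character vector of unique type names.
#' @slot included logical vector, parallel to `typeNames`.
#'
#' @seealso [functionTypeCatalog()], [defaultCatalog()]
#' @export
setClass("FunctionTypeCatalog",
  representation(typeNames = "character", included = "logical")
)

setValidity("FunctionTypeCatalog", function(object) {
  msg <- character()
  if (length(object@typeNames) == 0L)
    msg <- c(msg, "catalog must contain at least one type")
  if (anyDuplicated(object@typeNames))
    msg <- c(msg, "type names must be unique")
  if (length(object@included) != length(object@typeNames))
    msg <- c(msg, "'included' must be parallel to 'typeNames'")
  if (length(object@included) && !any(object@included))
    msg <- c(msg, "at least one type must be included")
  if (any(!nzchar(object@typeNames)))
    msg <- c(msg, "type names must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a function-type catalog
#'
#' @param typeNames character vector of type names.
#' @param included either a logical vector parallel to `typeNames` or a
#'   character vector naming the included types.
#' @return A [FunctionTypeCatalog-class] object.
#' @examples
#' functionTypeCatalog(c("uniprot_keyword", "interpro"))
#' @export
functionTypeCatalog <- function(typeNames, included = TRUE) {
  if (is.character(included)) {
    bad <- setdiff(included, typeNames)
    if (length(bad))
      stop("included types not in catalog: ", paste(bad, collapse = ", "))
    included <- typeNames %in% included
  }
  included <- rep_len(as.logical(included), length(typeNames))
  new("FunctionTypeCatalog", typeNames = as.character(typeNames),
      included = included)
}

#' The default nine-type catalog
#'
#' @param exclude character vector of type names whose `included` flag is
#'   dropped; defaults to SUPERFAMILY and ChEBI, whose single-type AUCs do
#'   not rise above chance.
#' @return A [FunctionTypeCatalog-class] with the nine standard vocabularies.
#' @examples
#' defaultCatalog()
#' defaultCatalog(exclude = character())  # keep all nine
#' @export
defaultCatalog <- function(exclude = .DEFAULT_EXCLUDED) {
  bad <- setdiff(exclude, .DEFAULT_TYPES)
  if (length(bad))
    stop("unknown type(s) in 'exclude': ", paste(bad, collapse = ", "))
  functionTypeCatalog(.DEFAULT_TYPES, !(.DEFAULT_TYPES %in% exclude))
}

#' @describeIn FunctionTypeCatalog-class all type names, in catalog order.
#' @param object,x a `FunctionTypeCatalog`.
#' @export
typeNames <- function(object) object@typeNames

#' @describeIn FunctionTypeCatalog-class names of the included types only.
#' @export
includedTypes <- function(object) object@typeNames[object@included]

setMethod("show", "FunctionTypeCatalog", function(object) {
  cat("FunctionTypeCatalog with", length(object@typeNames), "types (",
      sum(object@included), "included )\n")
  flag <- ifelse(object@included, "+", "-")
  cat(paste0("  [", flag, "] ", object@typeNames, collapse = "\n"), "\n")
})

#' Per-protein functional annotation table
#'
#' Holds, for each protein, the set of function identifiers it carries,
#' partitioned by function type. Internally stored as a de-duplicated long
#' data.frame (`protein_id`, `function_type`, `function_id`); each protein's
#' per-type set is the binary presence profile the prioritization algorithm
#' scores.
#'
#' @slot annotations data.frame with columns `protein_id`, `function_type`,
#'   `function_id`; rows unique, all fields non-empty, types drawn from the
#'   catalog.
#' @slot catalog the [FunctionTypeCatalog-class] the table was loaded
#'   against.
#'
#' @seealso [annotationTable()], [readAnnotations()]
#' @export
setClass("AnnotationTable",
  representation(annotations = "data.frame", catalog = "FunctionTypeCatalog")
)

setValidity("AnnotationTable", function(object) {
  ann <- object@annotations
  msg <- character()
  need <- c("protein_id", "function_type", "function_id")
  if (!identical(names(ann), need))
    return(paste("annotations must have columns", paste(need, collapse = ", ")))
  if (nrow(ann)) {
    if (any(!nzchar(ann$protein_id)) || any(!nzchar(ann$function_id)))
      msg <- c(msg, "protein and function ids must be non-empty")
    unknown <- setdiff(unique(ann$function_type), object@catalog@typeNames)
    if (length(unknown))
      msg <- c(msg, paste("unknown function type(s):",
                          paste(unknown, collapse = ", ")))
    if (anyDuplicated(ann))
      msg <- c(msg, "annotation rows must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an annotation table from a long data.frame
#'
#' @param annotations data.frame with columns `protein_id`, `function_type`,
#'   `function_id`. Duplicate rows are collapsed (annotation sets, not bags).
#' @param catalog a [FunctionTypeCatalog-class]; defaults to
#'   [defaultCatalog()].
#' @return An [AnnotationTable-class].
#' @export
annotationTable <- function(annotations, catalog = defaultCatalog()) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  annotations <- annotations[c("protein_id", "function_type", "function_id")]
  for (j in seq_along(annotations))
    annotations[[j]] <- as.character(annotations[[j]])
  annotations <- unique(annotations)
  rownames(annotations) <- NULL
  new("AnnotationTable", annotations = annotations, catalog = catalog)
}

#' @describeIn AnnotationTable-class the long-format annotation data.frame.
#' @param object,x an `AnnotationTable`.
#' @export
annotations <- function(object) object@annotations

#' @describeIn AnnotationTable-class the catalog the table was loaded against.
#' @export
catalog <- function(object) object@catalog

#' @describeIn AnnotationTable-class distinct protein accessions present.
#' @export
annotatedProteins <- function(object) unique(object@annotations$protein_id)

setMethod("show", "AnnotationTable", function(object) {
  ann <- object@annotations
  cat("AnnotationTable:", length(unique(ann$protein_id)), "proteins,",
      nrow(ann), "annotations across",
      length(unique(ann$function_type)), "function types\n")
})

#' One disease's protein set
#'
#' The set of proteins associated with a single Disease Ontology term,
#' merged across association sources. Its size `p` enters the priority-score
#' normalization.
#'
#' @slot diseaseId DOID identifier, e.g. `"DOID:10652"`.
#' @slot proteins character vector of unique protein accessions (at least 1).
#'
#' @seealso [assembleDatasets()]
#' @export
setClass("ProteinDiseaseDataset",
  representation(diseaseId = "character", proteins = "character")
)

setValidity("ProteinDiseaseDataset", function(object) {
  msg <- character()
  if (length(object@diseaseId) != 1L || !nzchar(object@diseaseId))
    msg <- c(msg, "diseaseId must be a single non-empty string")
  if (length(object@proteins) < 1L)
    msg <- c(msg, "dataset must contain at least one protein")
  if (anyDuplicated(object@proteins))
    msg <- c(msg, "proteins must be unique")
  if (any(!nzchar(object@proteins)))
    msg <- c(msg, "protein ids must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Construct a protein-disease dataset
#'
#' @param diseaseId DOID string.
#' @param proteins character vector of protein accessions; de-duplicated and
#'   sorted.
#' @return A [ProteinDiseaseDataset-class].
#' @export
proteinDiseaseDataset <- function(diseaseId, proteins) {
  new("ProteinDiseaseDataset", diseaseId = as.character(diseaseId),
      proteins = sort(unique(as.character(proteins))))
}

#' @describeIn ProteinDiseaseDataset-class the DOID of the dataset.
#' @param object,x a `ProteinDiseaseDataset`.
#' @export
diseaseId <- function(object) object@diseaseId

#' @describeIn ProteinDiseaseDataset-class the protein accessions.
#' @export
datasetProteins <- function(object) object@proteins

#' @describeIn ProteinDiseaseDataset-class the number of proteins `p`.
#' @export
nProteins <- function(object) length(object@proteins)

setMethod("show", "ProteinDiseaseDataset", function(object) {
  cat("ProteinDiseaseDataset", object@diseaseId, "with",
      length(object@proteins), "proteins\n")
})

#' Fitted priority-to-pertinency calibration model
#'
#' A weighted second-degree polynomial mapping a protein's priority score to
#' its predicted pertinency score (the probability-like fraction of proteins
#' in its score range that are targets of medications already indicated for
#' the disease).
#'
#' @slot coefficients named numeric of length 3 (`c0`, `c1`, `c2`), so that
#'   the prediction is `c2 * x^2 + c1 * x + c0`, clamped into `[0, 1]`.
#' @slot r Pearson correlation between observed bin pertinencies and fitted
#'   values.
#' @slot binEdges numeric vector of the score-bin edges used for the fit.
#' @slot foldSeed integer seed that produced the cross-validation folds.
#' @slot kFolds integer number of folds.
#'
#' @seealso [fitQuadratic()], [predictPertinency()]
#' @export
setClass("PertinencyModel",
  representation(coefficients = "numeric", r = "numeric",
                 binEdges = "numeric", foldSeed = "integer",
                 kFolds = "integer")
)

setValidity("PertinencyModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != 3L ||
      !identical(names(object@coefficients), c("c0", "c1", "c2")))
    msg <- c(msg, "coefficients must be named c0, c1, c2")
  if (length(object@r) != 1L || is.na(object@r) ||
      object@r < -1 || object@r > 1)
    msg <- c(msg, "r must be a single value in [-1, 1]")
  if (length(object@binEdges) >= 2L && any(diff(object@binEdges) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a pertinency model from known coefficients
#'
#' Mostly useful for applying a previously fitted calibration; models are
#' normally produced by [fitQuadratic()].
#'
#' @param c0,c1,c2 polynomial coefficients (intercept, linear, quadratic).
#' @param r correlation between observed and fitted bin means (default `NA`
#'   is not allowed; use 1 for an exact model).
#' @param binEdges,foldSeed,kFolds fit provenance; optional.
#' @return A [PertinencyModel-class].
#' @examples
#' m <- pertinencyModel(0.015, -0.110, 1.399, r = 0.9978)
#' predictPertinency(m, c(0, 0.25, 0.5))
#' @export
pertinencyModel <- function(c0, c1, c2, r = 1,
                            binEdges = numeric(), foldSeed = NA_integer_,
                            kFolds = NA_integer_) {
  new("PertinencyModel",
      coefficients = c(c0 = as.numeric(c0), c1 = as.numeric(c1),
                       c2 = as.numeric(c2)),
      r = as.numeric(r), binEdges = as.numeric(binEdges),
      foldSeed = as.integer(foldSeed), kFolds = as.integer(kFolds))
}

#' @describeIn PertinencyModel-class the `c0`, `c1`, `c2` coefficients.
#' @param object a `PertinencyModel`.
#' @export
modelCoefficients <- function(object) object@coefficients

#' @describeIn PertinencyModel-class correlation of observed vs fitted bin
#'   pertinencies.
#' @export
fitCorrelation <- function(object) object@r

setMethod("show", "PertinencyModel", function(object) {
  co <- object@coefficients
  cat(sprintf("PertinencyModel: y = %.4f x^2 %+.4f x %+.4f  (r = %.4f)\n",
              co[["c2"]], co[["c1"]], co[["c0"]], object@r))
})
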