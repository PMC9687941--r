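#' Assemble one protein-disease dataset per disease
#'
#' Collapses a disease-protein association table (possibly spanning several
#' sources such as OMIM, KEGG and DisGeNET) into one
#' [ProteinDiseaseDataset-class] per distinct disease, taking the union of
#' proteins across sources. The result is independent of row order and of
#' how pairs are duplicated across sources.
#'
#' @param table data.frame as returned by [readDiseaseProteins()].
#' @return named list of [ProteinDiseaseDataset-class], ordered by disease
#'   id.
#' @examples
#' tab <- data.frame(disease_id = c("DOID:1", "DOID:1", "DOID:2"),
#'                   protein_id = c("P1", "P2", "P1"),
#'                   source = c("omim", "kegg", "disgenet"))
#' ds <- assembleDatasets(tab)
#' nProteins(ds[["DOID:1"]])
#' @export
assembleDatasets <- function(table) {
  if (!nrow(table)) return(structure(list(), names = character()))
  .checkDoid(table$disease_id, "assembleDatasets")
  by_dis <- split(table$protein_id, table$disease_id)
  out <- lapply(names(by_dis), function(d)
    proteinDiseaseDataset(d, by_dis[[d]]))
  names(out) <- names(by_dis)
  out[order(names(out))]
}

#' Restrict datasets to those usable for validation and calibration
#'
#' Keeps the datasets with at least `minProteins` proteins, at least one
#' protein labelled a known drug target for the disease, and a disease id
#' not on the vague-disease exclusion list. The size and positive-label
#' requirements ensure enough data to estimate sensitivity and specificity
#' at each score threshold; the vague list removes nonspecific umbrella
#' terms (e.g. "cancer") whose protein sets mix unrelated mechanisms.
#'
#' @param datasets list of [ProteinDiseaseDataset-class] from
#'   [assembleDatasets()].
#' @param labels data.frame from [labelKnownTargets()] with columns
#'   `disease_id`, `protein_id`, `positive`.
#' @param vague character vector of DOIDs to exclude (default none).
#' @param minProteins minimum dataset size (default 30).
#' @return the surviving subset of `datasets`, order preserved.
#' @export
filterValidationDiseases <- function(datasets, labels,
                                     vague = character(),
                                     minProteins = 30L) {
  minProteins <- as.integer(minProteins)
  if (is.na(minProteins) || minProteins < 1L)
    stop("minProteins must be a positive integer")
  pos_by_disease <- tapply(labels$positive, labels$disease_id, sum)
  keep <- vapply(datasets, function(ds) {
    npos <- pos_by_disease[[diseaseId(ds)]]
    nProteins(ds) >= minProteins &&
      !is.null(npos) && !is.na(npos) && npos >= 1 &&
      !(diseaseId(ds) %in% vague)
  }, logical(1))
  datasets[keep]
}
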