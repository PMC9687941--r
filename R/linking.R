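#' Split a combination-medication name into component drugs
#'
#' Indication resources list combination products as a single record; each
#' component drug must be connected to its targets separately. Splits on
#' `/`, `+`, `;` and the token `" with "`, trims whitespace, and drops empty
#' components. Single-drug names come back as a singleton.
#'
#' @param drugName non-empty medication name.
#' @param delimiters regular expression of split points; the default covers
#'   the delimiters seen in practice and is deliberately a superset.
#' @return character vector of component names.
#' @examples
#' splitCombination("amlodipine / benazepril")
#' splitCombination("metformin")
#' @export
splitCombination <- function(drugName,
                             delimiters = "/|\\+|;|\\bwith\\b") {
  if (!nzchar(drugName)) stop("drug name must be non-empty")
  parts <- trimws(strsplit(drugName, delimiters)[[1L]])
  parts[nzchar(parts)]
}

.normalizeName <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  gsub("\\s*([[:punct:]])\\s*", "\\1", x)
}

#' Link indication records to drug-target identifiers
#'
#' Two-pass matching, mirroring how heterogeneous drug resources are
#' reconciled: records whose `drug_id` appears verbatim on the target side
#' link by identifier; the remainder link by case-insensitive,
#' whitespace-normalized generic-name equality after combination splitting.
#' A name that matches more than one target-side identifier is never linked
#' silently -- it lands in the ambiguity report attached to the result.
#'
#' @param indications data.frame from [readDrugIndications()].
#' @param targets data.frame from [readDrugTargets()].
#' @return data.frame with columns `indication_drug_id`, `target_drug_id`,
#'   `method` (`"id"` or `"name"`); ambiguous name matches are in
#'   `attr(, "ambiguities")` (columns `indication_drug_id`, `component`,
#'   `candidates`).
#' @export
matchDrugs <- function(indications, targets) {
  target_ids <- unique(targets$drug_id)
  recs <- unique(indications[c("drug_id", "drug_name")])

  by_id <- recs$drug_id %in% target_ids
  links <- data.frame(indication_drug_id = recs$drug_id[by_id],
                      target_drug_id = recs$drug_id[by_id],
                      method = if (any(by_id)) "id" else character(),
                      stringsAsFactors = FALSE)

  norm_targets <- split(target_ids, .normalizeName(target_ids))
  amb <- data.frame(indication_drug_id = character(),
                    component = character(), candidates = character(),
                    stringsAsFactors = FALSE)
  unmatched <- recs[!by_id, , drop = FALSE]
  for (i in seq_len(nrow(unmatched))) {
    comps <- splitCombination(unmatched$drug_name[i])
    for (comp in comps) {
      hit <- norm_targets[[.normalizeName(comp)]]
      if (is.null(hit)) next
      if (length(hit) > 1L) {
        amb <- rbind(amb, data.frame(
          indication_drug_id = unmatched$drug_id[i], component = comp,
          candidates = paste(sort(hit), collapse = ","),
          stringsAsFactors = FALSE))
      } else {
        links <- rbind(links, data.frame(
          indication_drug_id = unmatched$drug_id[i],
          target_drug_id = hit, method = "name",
          stringsAsFactors = FALSE))
      }
    }
  }
  links <- unique(links)
  rownames(links) <- NULL
  attr(links, "ambiguities") <- amb
  links
}

#' Medications eligible per disease
#'
#' A medication is eligible for a disease when it is on the market (phase
#' 4), not withdrawn, and at least one of its indication codes maps to the
#' disease through the ICD-to-DOID cross-references. An ICD code that maps
#' to several DOIDs attaches the indication to all of them.
#'
#' @param indications data.frame from [readDrugIndications()].
#' @param icdMap named list from [readDoOboXrefs()].
#' @param matches optional link table from [matchDrugs()]; when given, drug
#'   ids are translated to target-side ids (unlinked records keep their own
#'   id).
#' @return named list: disease id -> sorted character vector of eligible
#'   drug ids.
#' @export
eligibleMedications <- function(indications, icdMap, matches = NULL) {
  ok <- indications$phase == 4L & !indications$withdrawn
  ind <- indications[ok, , drop = FALSE]
  if (!nrow(ind)) return(structure(list(), names = character()))
  drug <- ind$drug_id
  if (!is.null(matches) && nrow(matches)) {
    m <- match(drug, matches$indication_drug_id)
    drug <- ifelse(is.na(m), drug, matches$target_drug_id[m])
  }
  doids <- icdMap[ind$indication_code]
  n <- lengths(doids)
  keep <- n > 0L & !is.na(names(doids))
  if (!any(keep)) return(structure(list(), names = character()))
  long <- data.frame(disease_id = unlist(doids[keep], use.names = FALSE),
                     drug_id = rep(drug[keep], n[keep]),
                     stringsAsFactors = FALSE)
  out <- lapply(split(long$drug_id, long$disease_id),
                function(v) sort(unique(v)))
  out[order(names(out))]
}

#' Label each dataset protein as a known drug target or not
#'
#' A protein is positive for its disease when it is targeted by at least one
#' medication in that disease's eligible set; all other dataset proteins are
#' negative. These labels are the ground truth for the ROC validation and
#' for the pertinency score.
#'
#' @param datasets list of [ProteinDiseaseDataset-class].
#' @param eligible named list from [eligibleMedications()].
#' @param targets data.frame from [readDrugTargets()].
#' @return data.frame with columns `disease_id`, `protein_id`, `positive`
#'   (logical), one row per dataset protein.
#' @export
labelKnownTargets <- function(datasets, eligible, targets) {
  targets_by_drug <- split(targets$protein_id, targets$drug_id)
  res <- lapply(datasets, function(ds) {
    drugs <- eligible[[diseaseId(ds)]]
    hit <- unique(unlist(targets_by_drug[drugs], use.names = FALSE))
    data.frame(disease_id = diseaseId(ds),
               protein_id = datasetProteins(ds),
               positive = datasetProteins(ds) %in% hit,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(disease_id = character(), protein_id = character(),
                      positive = logical(), stringsAsFactors = FALSE)
  out
}
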