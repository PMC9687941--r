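#' Ranked repositioning candidates for one disease
#'
#' Pairs every scored protein of the disease with the drugs that target it,
#' predicts the pertinency of each pair from the calibration model, keeps
#' pairs at or above the decision threshold, and flags each drug as a
#' `known_indication` (already eligible for this disease) or a `candidate`
#' (a repositioning hypothesis). Whether a candidate would oppose or
#' exacerbate the aberrant protein function is deliberately left to the
#' user; no mechanism flag is emitted.
#'
#' @param diseaseIdStr the DOID to report on.
#' @param scored data.frame from [scoreDiseases()] covering the disease.
#' @param model a fitted [PertinencyModel-class].
#' @param targets data.frame from [readDrugTargets()].
#' @param eligible named list from [eligibleMedications()].
#' @param minPertinency decision threshold on predicted pertinency
#'   (default 0.1, the empirically recommended starting point).
#' @param drugNames optional named character vector mapping drug ids to
#'   display names; ids are used where no name is known.
#' @return data.frame with columns `disease_id`, `protein_id`, `drug_id`,
#'   `drug_name`, `priority`, `predicted_pertinency`, `status`, sorted by
#'   descending predicted pertinency, then protein id, then drug id.
#' @export
repurpose <- function(diseaseIdStr, scored, model, targets, eligible,
                      minPertinency = 0.1, drugNames = NULL) {
  sc <- scored[scored$disease_id == diseaseIdStr, , drop = FALSE]
  if (!nrow(sc)) stop("no scored proteins for disease ", diseaseIdStr)
  sc$predicted_pertinency <- predictPertinency(model, sc$priority)
  sc <- sc[sc$predicted_pertinency >= minPertinency, , drop = FALSE]
  hit <- targets[targets$protein_id %in% sc$protein_id, , drop = FALSE]
  if (!nrow(sc) || !nrow(hit))
    return(data.frame(disease_id = character(), protein_id = character(),
                      drug_id = character(), drug_name = character(),
                      priority = numeric(), predicted_pertinency = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  m <- match(hit$protein_id, sc$protein_id)
  known <- eligible[[diseaseIdStr]]
  nm <- hit$drug_id
  if (!is.null(drugNames)) {
    named <- !is.na(drugNames[nm])
    nm[named] <- drugNames[nm[named]]
  }
  out <- data.frame(
    disease_id = diseaseIdStr, protein_id = hit$protein_id,
    drug_id = hit$drug_id, drug_name = nm,
    priority = sc$priority[m],
    predicted_pertinency = sc$predicted_pertinency[m],
    status = ifelse(hit$drug_id %in% known, "known_indication", "candidate"),
    stringsAsFactors = FALSE)
  ord <- order(-out$predicted_pertinency, out$protein_id, out$drug_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repositioning reports for every disease
#'
#' @param scored data.frame from [scoreDiseases()].
#' @param model a fitted [PertinencyModel-class].
#' @inheritParams repurpose
#' @return stacked [repurpose()] rows across all scored diseases.
#' @export
repurposeAll <- function(scored, model, targets, eligible,
                         minPertinency = 0.1, drugNames = NULL) {
  rows <- lapply(unique(scored$disease_id), repurpose, scored = scored,
                 model = model, targets = targets, eligible = eligible,
                 minPertinency = minPertinency, drugNames = drugNames)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Top repositioning candidates across all diseases
#'
#' Because the calibration is one global model, predicted pertinencies are
#' comparable across diseases and candidates can be ranked globally. Ties
#' are broken lexicographically on (disease, protein, drug).
#'
#' @param allRows stacked [repurpose()] rows.
#' @param k number of candidates to return (>= 1).
#' @return the top `k` rows with `status == "candidate"`.
#' @export
topCandidates <- function(allRows, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  cand <- allRows[allRows$status == "candidate", , drop = FALSE]
  ord <- order(-cand$predicted_pertinency, cand$disease_id,
               cand$protein_id, cand$drug_id, method = "radix")
  out <- cand[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
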