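#' Enumerate known drug/protein/disease tuples under one snapshot
#'
#' A tuple (drug, protein, disease) is known when the protein belongs to
#' the disease's dataset, the drug targets the protein, and the drug is
#' eligible (on-market, indication mapping to the disease) under the given
#' indication snapshot. Comparing the tuple sets of two snapshots taken at
#' different times reveals where newly adopted indications fell on the
#' pertinency scale.
#'
#' @param targets data.frame from [readDrugTargets()].
#' @param eligible named list from [eligibleMedications()] for one snapshot.
#' @param datasets list of [ProteinDiseaseDataset-class].
#' @return data.frame with columns `drug_id`, `protein_id`, `disease_id`
#'   (unique rows).
#' @export
knownTuples <- function(targets, eligible, datasets) {
  targets_by_drug <- split(targets$protein_id, targets$drug_id)
  rows <- lapply(datasets, function(ds) {
    drugs <- intersect(eligible[[diseaseId(ds)]], names(targets_by_drug))
    if (!length(drugs)) return(NULL)
    hits <- lapply(drugs, function(dr)
      intersect(targets_by_drug[[dr]], datasetProteins(ds)))
    n <- lengths(hits)
    if (!sum(n)) return(NULL)
    data.frame(drug_id = rep(drugs, n),
               protein_id = unlist(hits, use.names = FALSE),
               disease_id = diseaseId(ds), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(drug_id = character(), protein_id = character(),
                      disease_id = character(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  rownames(out) <- NULL
  out
}

.tupleKey <- function(t) paste(t$drug_id, t$protein_id, t$disease_id,
                               sep = "\r")

#' Bin snapshot-to-snapshot new tuples by predicted pertinency
#'
#' Takes the tuples present under the later snapshot but absent under the
#' earlier one, bins each by the predicted pertinency of its (disease,
#' protein) pair under the earlier snapshot (the prospective framing: could
#' the early model have pointed at the adoption to come?), and divides each
#' bin's count of new tuples by the number of scored (disease, protein)
#' target pairs in the bin.
#'
#' @param tuplesA,tuplesB tuple data.frames from [knownTuples()] for the
#'   earlier and later snapshots.
#' @param predicted data.frame with columns `disease_id`, `protein_id`,
#'   `predicted_pertinency`: the snapshot-A predictions for every scored
#'   (disease, protein) target pair; these rows are the bin denominators.
#' @param binWidth pertinency bin width; must divide 1 evenly (default 0.1).
#' @return data.frame with columns `bin_lo`, `bin_hi`, `n_new_tuples`,
#'   `n_targets`, `ratio` (`NA` where `n_targets == 0`); new tuples whose
#'   pair has no snapshot-A prediction are counted in a final "unscored"
#'   row with `NA` edges.
#' @export
newTupleRatios <- function(tuplesA, tuplesB, predicted, binWidth = 0.1) {
  nb <- 1 / binWidth
  if (abs(nb - round(nb)) > 1e-9)
    stop("binWidth must divide 1 evenly; got ", binWidth)
  nb <- as.integer(round(nb))
  edges <- seq(0, 1, length.out = nb + 1L)

  new_keys <- setdiff(.tupleKey(tuplesB), .tupleKey(tuplesA))
  new <- tuplesB[.tupleKey(tuplesB) %in% new_keys, , drop = FALSE]

  pair_key <- paste(predicted$disease_id, predicted$protein_id, sep = "\r")
  pair_bin <- findInterval(predicted$predicted_pertinency, edges,
                           rightmost.closed = TRUE)
  new_bin <- pair_bin[match(paste(new$disease_id, new$protein_id,
                                  sep = "\r"), pair_key)]

  n_new <- tabulate(new_bin[!is.na(new_bin)], nbins = nb)
  n_targets <- tabulate(pair_bin, nbins = nb)
  out <- data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
                    n_new_tuples = n_new, n_targets = n_targets,
                    ratio = ifelse(n_targets > 0, n_new / n_targets,
                                   NA_real_))
  n_unscored <- sum(is.na(new_bin))
  if (n_unscored)
    out <- rbind(out, data.frame(bin_lo = NA_real_, bin_hi = NA_real_,
                                 n_new_tuples = n_unscored,
                                 n_targets = 0L, ratio = NA_real_))
  out
}

#' Recommend a pertinency decision threshold from the ratio table
#'
#' Scans the bins in score order and returns the lower edge of the first
#' bin whose new-tuple ratio exceeds the last defined preceding ratio by
#' the jump factor -- the point where newly adopted indications start
#' concentrating. When no such jump exists the conventional default of 0.1
#' is returned with a warning.
#'
#' @param table data.frame from [newTupleRatios()] (at least 2 defined
#'   bins).
#' @param jumpFactor multiplicative jump that counts as "large" (default 2).
#' @return the recommended threshold (a bin lower edge).
#' @export
recommendThreshold <- function(table, jumpFactor = 2) {
  tab <- table[!is.na(table$bin_lo), , drop = FALSE]
  def <- which(!is.na(tab$ratio))
  if (length(def) < 2L)
    stop("need at least two bins with defined ratios")
  prev <- tab$ratio[def[1L]]
  for (i in def[-1L]) {
    cur <- tab$ratio[i]
    if ((prev == 0 && cur > 0) || (prev > 0 && cur > jumpFactor * prev))
      return(tab$bin_lo[i])
    prev <- cur
  }
  warning("no ratio jump of factor ", jumpFactor,
          " found; falling back to threshold 0.1")
  0.1
}

#' Write a ratio table as TSV
#'
#' @param table data.frame from [newTupleRatios()].
#' @param path output path (`ratios.tsv`).
#' @return the path, invisibly.
#' @export
writeRatioTable <- function(table, path) {
  df <- data.frame(
    bin_lo = ifelse(is.na(table$bin_lo), "unscored",
                    sprintf("%.6f", table$bin_lo)),
    bin_hi = ifelse(is.na(table$bin_hi), "",
                    sprintf("%.6f", table$bin_hi)),
    n_new_tuples = table$n_new_tuples, n_targets = table$n_targets,
    ratio = ifelse(is.na(table$ratio), "", sprintf("%.6f", table$ratio)),
    stringsAsFactors = FALSE)
  .writeTsv(df, path)
}
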