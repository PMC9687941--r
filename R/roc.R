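#' ROC curve and AUC of priority scores against known-target labels
#'
#' Thresholds are the distinct observed scores (tied scores share a
#' threshold, i.e. one ROC vertex per distinct score). The AUC is computed
#' with the rank statistic `U / (n_pos * n_neg)` with ties given half
#' credit, which equals the trapezoidal area under the threshold-wise curve.
#'
#' @param scores numeric vector of priority scores.
#' @param labels logical vector, `TRUE` for known targets; needs at least
#'   one positive and one negative.
#' @param diseaseIdLabel optional id used in error messages and the result.
#' @return list with elements `disease_id`, `auc`, `n_pos`, `n_neg`, and
#'   `curve`, a data.frame of (`fpr`, `tpr`) points from (0,0) to (1,1).
#' @examples
#' rocAuc(c(3, 2, 1), c(TRUE, FALSE, FALSE))$auc  # perfect separation
#' @export
rocAuc <- function(scores, labels, diseaseIdLabel = NA_character_) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined for ",
         if (is.na(diseaseIdLabel)) "this dataset" else diseaseIdLabel,
         ": needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # predicted positive when score >= threshold, one threshold per distinct
  # score, descending; prepend the all-negative operating point
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(disease_id = diseaseIdLabel, auc = auc,
       n_pos = n_pos, n_neg = n_neg, curve = curve)
}

#' Summarize per-disease AUCs with a one-sample t-test against 0.5
#'
#' @param aucs numeric vector of per-disease AUCs (at least 2).
#' @return one-row data.frame: `n_diseases`, `mean_auc`, `sd_auc`,
#'   `p_value` (two-sided t-test of the mean against the no-discrimination
#'   value 0.5). With zero variance the test statistic is undefined; the
#'   row carries `p_value = 1` and a warning is raised.
#' @export
meanAucTtest <- function(aucs) {
  aucs <- as.numeric(aucs)
  if (length(aucs) < 2L)
    stop("need at least two AUC values to test against 0.5")
  m <- mean(aucs)
  s <- stats::sd(aucs)
  if (s == 0) {
    warning("zero variance among AUCs; t-test undefined, reporting p = 1")
    p <- 1
  } else {
    p <- stats::t.test(aucs, mu = 0.5)$p.value
  }
  data.frame(n_diseases = length(aucs), mean_auc = m, sd_auc = s,
             p_value = p)
}

#' Per-disease AUC for a collection of scored datasets
#'
#' @param datasets list of validation [ProteinDiseaseDataset-class] (each
#'   must have both label classes).
#' @param ann an [AnnotationTable-class].
#' @param labels data.frame from [labelKnownTargets()].
#' @param catalog optional [FunctionTypeCatalog-class].
#' @return data.frame with columns `disease_id`, `auc`, `n_pos`, `n_neg`.
#' @export
rocTable <- function(datasets, ann, labels, catalog = NULL) {
  lab_key <- paste(labels$disease_id, labels$protein_id)
  rows <- lapply(datasets, function(ds) {
    sc <- finalPriority(ds, ann, catalog)
    pos <- labels$positive[match(paste(sc$disease_id, sc$protein_id),
                                 lab_key)]
    r <- rocAuc(sc$priority, pos, diseaseId(ds))
    data.frame(disease_id = r$disease_id, auc = r$auc,
               n_pos = r$n_pos, n_neg = r$n_neg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Function-type ablation of the priority score
#'
#' Re-scores every validation dataset under each configuration (subset of
#' function types), computes per-disease AUCs, and summarizes each
#' configuration with [meanAucTtest()]. Used to decide which annotation
#' vocabularies contribute discrimination; configurations whose AUC does
#' not rise above 0.5 are candidates for exclusion from the default
#' catalog.
#'
#' @param datasets list of validation datasets (apply
#'   [filterValidationDiseases()] first).
#' @param ann an [AnnotationTable-class].
#' @param labels data.frame from [labelKnownTargets()].
#' @param configs named list of character vectors of type names; e.g.
#'   `list(all = typeNames(cat), keywords_only = "uniprot_keyword")`.
#' @return data.frame with one row per configuration: `config`,
#'   `n_diseases`, `mean_auc`, `sd_auc`, `p_value`. A configuration usable
#'   in no dataset yields an all-`NA` row (flagged empty).
#' @export
runAblation <- function(datasets, ann, labels, configs) {
  if (!length(configs)) stop("config list must be non-empty")
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    stop("configs must be a named list")
  rows <- lapply(names(configs), function(cfg) {
    cat_cfg <- functionTypeCatalog(configs[[cfg]])
    aucs <- numeric()
    for (ds in datasets) {
      sc <- suppressWarnings(finalPriority(ds, ann, cat_cfg))
      if (all(sc$n_types_used == 0L)) next   # type absent from dataset
      key <- paste(labels$disease_id, labels$protein_id)
      pos <- labels$positive[match(paste(sc$disease_id, sc$protein_id), key)]
      aucs <- c(aucs, rocAuc(sc$priority, pos, diseaseId(ds))$auc)
    }
    if (length(aucs) < 2L)
      return(data.frame(config = cfg, n_diseases = length(aucs),
                        mean_auc = NA_real_, sd_auc = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    cbind(config = cfg, meanAucTtest(aucs), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
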