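.requireInput <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "': missing input file ", path)
  path
}

.md5 <- function(paths) {
  h <- tools::md5sum(paths)
  names(h) <- basename(paths)
  as.list(h)
}

#' Run the whole prioritization and repositioning pipeline
#'
#' Executes, in order: input loading, dataset assembly, priority scoring of
#' every disease, drug linking and known-target labelling, validation
#' filtering and per-disease ROC, pertinency-model fitting, pertinency
#' prediction, two-snapshot threshold analysis (when a second indication
#' snapshot is present), and repositioning-report generation. Writes
#' `scored.tsv`, `roc.tsv`, `model.json`, `ratios.tsv` (if applicable),
#' `repositioning.tsv` and a `manifest.json` with input checksums and
#' seeds. Failures stop with the stage name; all randomness (fold
#' assignment) flows from `seed`.
#'
#' @param inputDir directory with `annotations.tsv`,
#'   `disease_proteins.tsv`, `drug_targets.tsv`, `drug_indications_a.tsv`
#'   (or `drug_indications.tsv`), optionally `drug_indications_b.tsv`, and
#'   `doid.obo`; [simulateInputs()] produces exactly this layout.
#' @param outDir output directory (created if missing).
#' @param seed integer seed for fold assignment.
#' @param minProteins validation dataset size floor (default 30).
#' @param kBins,kFolds calibration bin and fold counts (defaults 6, 6).
#' @param minPertinency repositioning decision threshold (default 0.1).
#' @param vague character vector of vague disease ids to exclude from
#'   validation (default none).
#' @param catalog optional [FunctionTypeCatalog-class]; defaults to
#'   [defaultCatalog()].
#' @return invisibly, a list with the in-memory stage results: `datasets`,
#'   `scored`, `labels`, `roc`, `model`, `ratios` (or `NULL`),
#'   `threshold` (or `NA`), `repositioning`, and `outputs` (file paths).
#' @export
runAll <- function(inputDir, outDir, seed = 1L, minProteins = 30L,
                   kBins = 6L, kFolds = 6L, minPertinency = 0.1,
                   vague = character(), catalog = defaultCatalog()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # ---- load
  ind_a_path <- file.path(inputDir, "drug_indications_a.tsv")
  if (!file.exists(ind_a_path))
    ind_a_path <- file.path(inputDir, "drug_indications.tsv")
  paths <- c(annotations = .requireInput(
               file.path(inputDir, "annotations.tsv"), "load"),
             disease_proteins = .requireInput(
               file.path(inputDir, "disease_proteins.tsv"), "load"),
             drug_targets = .requireInput(
               file.path(inputDir, "drug_targets.tsv"), "load"),
             drug_indications_a = .requireInput(ind_a_path, "load"),
             doid = .requireInput(file.path(inputDir, "doid.obo"), "load"))
  ann <- readAnnotations(paths[["annotations"]], catalog)
  dis_prot <- readDiseaseProteins(paths[["disease_proteins"]])
  targets <- readDrugTargets(paths[["drug_targets"]])
  ind_a <- readDrugIndications(paths[["drug_indications_a"]])
  icd <- readDoOboXrefs(paths[["doid"]])
  ind_b_path <- file.path(inputDir, "drug_indications_b.tsv")
  ind_b <- if (file.exists(ind_b_path)) readDrugIndications(ind_b_path)
           else NULL

  # ---- assemble & score
  datasets <- assembleDatasets(dis_prot)
  if (!length(datasets)) stop("stage 'assemble': no datasets")
  scored <- scoreDiseases(datasets, ann, catalog)

  # ---- link & label
  matches_a <- matchDrugs(ind_a, targets)
  eligible_a <- eligibleMedications(ind_a, icd, matches_a)
  labels <- labelKnownTargets(datasets, eligible_a, targets)

  # ---- validate
  validation <- filterValidationDiseases(datasets, labels, vague,
                                         minProteins)
  if (length(validation) < max(2L, kFolds))
    stop("stage 'validate': only ", length(validation),
         " validation dataset(s); need at least ", max(2L, kFolds))
  roc <- rocTable(validation, ann, labels, catalog)
  .writeTsv(data.frame(disease_id = roc$disease_id,
                       auc = sprintf("%.6f", roc$auc),
                       n_pos = roc$n_pos, n_neg = roc$n_neg),
            file.path(outDir, "roc.tsv"))

  # ---- fit & predict
  val_ids <- vapply(validation, diseaseId, character(1))
  model <- fitPertinencyModel(scored[scored$disease_id %in% val_ids, ],
                              labels, kBins = kBins, kFolds = kFolds,
                              seed = seed)
  writeModelJson(model, file.path(outDir, "model.json"))
  scored$predicted_pertinency <- predictPertinency(model, scored$priority)
  key <- paste(labels$disease_id, labels$protein_id)
  scored$known_target <- labels$positive[
    match(paste(scored$disease_id, scored$protein_id), key)]
  writeScoredTable(scored, file.path(outDir, "scored.tsv"))

  # ---- threshold (needs the later snapshot)
  ratios <- NULL
  threshold <- NA_real_
  if (!is.null(ind_b)) {
    matches_b <- matchDrugs(ind_b, targets)
    eligible_b <- eligibleMedications(ind_b, icd, matches_b)
    tuples_a <- knownTuples(targets, eligible_a, datasets)
    tuples_b <- knownTuples(targets, eligible_b, datasets)
    is_target <- scored$protein_id %in% unique(targets$protein_id)
    predicted <- scored[is_target, c("disease_id", "protein_id",
                                     "predicted_pertinency")]
    ratios <- newTupleRatios(tuples_a, tuples_b, predicted)
    writeRatioTable(ratios, file.path(outDir, "ratios.tsv"))
    threshold <- tryCatch(recommendThreshold(ratios),
                          warning = function(w) {
                            message("threshold: ", conditionMessage(w))
                            0.1
                          },
                          error = function(e) {
                            message("threshold: ", conditionMessage(e))
                            NA_real_
                          })
  }

  # ---- repurpose
  drug_names <- stats::setNames(ind_a$drug_name, ind_a$drug_id)
  drug_names <- drug_names[!duplicated(names(drug_names))]
  reps <- repurposeAll(scored, model, targets, eligible_a,
                       minPertinency = minPertinency,
                       drugNames = drug_names)
  .writeTsv(data.frame(
    disease_id = reps$disease_id, protein_id = reps$protein_id,
    drug_id = reps$drug_id, drug_name = reps$drug_name,
    priority = sprintf("%.6f", reps$priority),
    predicted_pertinency = sprintf("%.6f", reps$predicted_pertinency),
    status = reps$status), file.path(outDir, "repositioning.tsv"))

  manifest <- list(
    tool = "pharmacorank",
    version = as.character(utils::packageVersion("pharmacorank")),
    seed = as.integer(seed),
    parameters = list(min_proteins = as.integer(minProteins),
                      k_bins = as.integer(kBins),
                      k_folds = as.integer(kFolds),
                      min_pertinency = minPertinency),
    inputs = .md5(unname(paths)),
    n_datasets = length(datasets),
    n_validation = length(validation),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(datasets = datasets, scored = scored, labels = labels,
                 roc = roc, model = model, ratios = ratios,
                 threshold = threshold, repositioning = reps,
                 outputs = list.files(outDir, full.names = TRUE)))
}
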