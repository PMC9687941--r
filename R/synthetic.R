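## Synthetic inputs with a plantable "druggable core": within each disease a
## fraction of the proteins (the core) draw part of their annotations from a
## small pool of functions shared across core proteins, and it is mostly the
## core that receives drugs and on-market indications. The enrichment
## multiplier controls how much more often core proteins use the pool than
## peripheral proteins do; at multiplier 1 core and periphery are
## statistically exchangeable and the generator is an exact null.

.simDefaults <- list(
  nDiseases = 100L,
  proteinsPerDisease = 45,      # Poisson mean, floored at 30
  vocabularySizePerType = 200L, # background vocabulary (Zipf-used)
  zipfExponent = 0.7,           # background usage skew (rank^-s)
  annotationsPerProteinPerType = 5,  # Poisson mean
  coreFraction = 0.2,
  coreEnrichment = 8,
  poolSize = 8L,                # shared druggable-core functions per type
  basePoolProb = 0.06,          # peripheral per-annotation pool probability
  drugPerCoreProteinProb = 0.8,
  peripheralDrugProb = 0.05,
  indicationProb = 0.7,         # P(drug gets an on-market indication, snap A)
  snapshotBExtraIndicationProb = 0.15,
  phase3Prob = 0.05,
  withdrawnProb = 0.03
)

.simConfig <- function(...) {
  cfg <- utils::modifyList(.simDefaults, list(...))
  probs <- c("coreFraction", "basePoolProb", "drugPerCoreProteinProb",
             "peripheralDrugProb", "indicationProb",
             "snapshotBExtraIndicationProb", "phase3Prob", "withdrawnProb")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  for (p in c("nDiseases", "proteinsPerDisease", "vocabularySizePerType",
              "annotationsPerProteinPerType", "poolSize", "coreEnrichment"))
    if (cfg[[p]] <= 0) stop(p, " must be positive")
  if (cfg$poolSize > cfg$vocabularySizePerType)
    stop("poolSize cannot exceed vocabularySizePerType")
  cfg
}

## Annotation structure + disease membership; all randomness from the
## caller-set RNG state.
.simulateStructure <- function(cfg) {
  types <- .DEFAULT_TYPES
  zipf <- seq_len(cfg$vocabularySizePerType)^(-cfg$zipfExponent)
  ann <- vector("list", cfg$nDiseases * length(types))
  membership <- vector("list", cfg$nDiseases)
  ai <- 0L
  for (d in seq_len(cfg$nDiseases)) {
    p <- max(30L, stats::rpois(1L, cfg$proteinsPerDisease))
    prot <- sprintf("P%03d_%03d", d, seq_len(p))
    n_core <- max(1L, round(cfg$coreFraction * p))
    core <- c(rep(TRUE, n_core), rep(FALSE, p - n_core))
    membership[[d]] <- data.frame(
      disease_id = sprintf("DOID:%d", d), protein_id = prot, core = core,
      stringsAsFactors = FALSE)
    pi_core <- min(1, cfg$coreEnrichment * cfg$basePoolProb)
    pi_prot <- ifelse(core, pi_core, cfg$basePoolProb)
    for (ty in types) {
      n_fun <- stats::rpois(p, cfg$annotationsPerProteinPerType)
      tot <- sum(n_fun)
      if (!tot) next
      who <- rep(seq_len(p), n_fun)
      from_pool <- stats::runif(tot) < pi_prot[who]
      fid <- integer(tot)
      if (any(from_pool))
        fid[from_pool] <- sample.int(cfg$poolSize, sum(from_pool),
                                     replace = TRUE)
      if (any(!from_pool))
        fid[!from_pool] <- sample.int(cfg$vocabularySizePerType,
                                      sum(!from_pool), replace = TRUE,
                                      prob = zipf)
      ai <- ai + 1L
      ann[[ai]] <- data.frame(
        protein_id = prot[who], function_type = ty,
        function_id = sprintf("%s:%04d", toupper(substr(ty, 1L, 2L)), fid),
        pool = from_pool, stringsAsFactors = FALSE)
    }
  }
  annotations <- unique(do.call(rbind, ann[seq_len(ai)]))
  rownames(annotations) <- NULL
  list(annotations = annotations,
       membership = do.call(rbind, membership))
}

.enrichmentCheck <- function(structure, cfg) {
  if (cfg$coreEnrichment <= 2) return(invisible(NULL))
  mem_key <- structure$membership$core[
    match(structure$annotations$protein_id,
          structure$membership$protein_id)]
  tab <- table(core = mem_key, pool = structure$annotations$pool)
  if (!all(dim(tab) == c(2L, 2L))) return(invisible(NULL))
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  if (is.na(p) || p > 0.01)
    warning("planted core enrichment not detected (chi-squared p = ",
            signif(p, 3), "); consider a larger problem size")
  invisible(NULL)
}

#' Generate a full set of synthetic pipeline inputs
#'
#' Writes `annotations.tsv`, `disease_proteins.tsv`, `drug_targets.tsv`,
#' two indication snapshots (`drug_indications_a.tsv`,
#' `drug_indications_b.tsv`, the later a superset of the earlier), a
#' minimal `doid.obo` mapping one ICD code to each disease, and a
#' `truth.json` sidecar recording the planted configuration. Identical
#' seeds yield byte-identical directories.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed governing all randomness.
#' @param ... configuration overrides; see Details.
#' @details Tunables (defaults in parentheses): `nDiseases` (100),
#'   `proteinsPerDisease` (Poisson mean 45, floored at 30),
#'   `vocabularySizePerType` (200), `annotationsPerProteinPerType` (Poisson
#'   mean 5), `coreFraction` (0.2), `coreEnrichment` (8), `poolSize` (8),
#'   `zipfExponent` (0.7, background annotation-usage skew),
#'   `basePoolProb` (0.06), `drugPerCoreProteinProb` (0.8),
#'   `peripheralDrugProb` (0.05), `indicationProb` (0.7),
#'   `snapshotBExtraIndicationProb` (0.15), `phase3Prob` (0.05),
#'   `withdrawnProb` (0.03). With `coreEnrichment = 1` the annotation
#'   pattern carries no information about drug targeting (a null
#'   generator).
#' @return the directory path, invisibly; the file set as attribute
#'   `files`.
#' @export
simulateInputs <- function(dir, seed = 1L, ...) {
  cfg <- .simConfig(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(seed, {
    structure <- .simulateStructure(cfg)
    .enrichmentCheck(structure, cfg)
    mem <- structure$membership

    # association sources; ~10% of pairs are reported by a second source
    src <- sample(c("omim", "kegg", "disgenet"), nrow(mem), replace = TRUE,
                  prob = c(0.1, 0.05, 0.85))
    dis_prot <- data.frame(disease_id = mem$disease_id,
                           protein_id = mem$protein_id, source = src,
                           stringsAsFactors = FALSE)
    dup <- stats::runif(nrow(mem)) < 0.1
    if (any(dup)) {
      extra <- dis_prot[dup, , drop = FALSE]
      extra$source <- ifelse(extra$source == "omim", "disgenet", "omim")
      dis_prot <- rbind(dis_prot, extra)
    }

    # drugs: mostly on core proteins; one drug per targeted protein
    drug_prob <- ifelse(mem$core, cfg$drugPerCoreProteinProb,
                        cfg$peripheralDrugProb)
    targeted <- stats::runif(nrow(mem)) < drug_prob
    tg <- mem[targeted, , drop = FALSE]
    tg$drug_id <- sprintf("DRG_%s", tg$protein_id)
    drug_targets <- data.frame(drug_id = tg$drug_id,
                               protein_id = tg$protein_id,
                               stringsAsFactors = FALSE)

    # indications: snapshot A, then B = A plus later adoptions
    icd <- sub("^DOID:", "ICD10CM:X", tg$disease_id)
    phase <- ifelse(stats::runif(nrow(tg)) < cfg$phase3Prob, 3L, 4L)
    withdrawn <- stats::runif(nrow(tg)) < cfg$withdrawnProb
    in_a <- stats::runif(nrow(tg)) < cfg$indicationProb
    extra_b <- !in_a & stats::runif(nrow(tg)) < cfg$snapshotBExtraIndicationProb
    ind <- data.frame(drug_id = tg$drug_id,
                      drug_name = tolower(gsub("_", " ", tg$drug_id)),
                      indication_code = icd, phase = phase,
                      withdrawn = as.integer(withdrawn),
                      stringsAsFactors = FALSE)
    ind_a <- ind[in_a, , drop = FALSE]
    ind_b <- ind[in_a | extra_b, , drop = FALSE]

    obo <- c("format-version: 1.2", "")
    for (d in seq_len(cfg$nDiseases))
      obo <- c(obo, "[Term]", sprintf("id: DOID:%d", d),
               sprintf("name: synthetic disease %d", d),
               sprintf("xref: ICD10CM:X%d", d), "")

    files <- file.path(dir, c("annotations.tsv", "disease_proteins.tsv",
                              "drug_targets.tsv", "drug_indications_a.tsv",
                              "drug_indications_b.tsv", "doid.obo",
                              "truth.json"))
    .writeTsv(structure$annotations[
      c("protein_id", "function_type", "function_id")], files[1L])
    .writeTsv(dis_prot, files[2L])
    .writeTsv(drug_targets, files[3L])
    .writeTsv(ind_a, files[4L])
    .writeTsv(ind_b, files[5L])
    con <- file(files[6L], open = "wb")
    writeLines(obo, con, sep = "\n")
    close(con)
    jsonlite::write_json(c(list(seed = as.integer(seed)), cfg,
                           list(core_proteins = sum(mem$core),
                                total_proteins = nrow(mem))),
                         files[7L], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    attr(dir, "files") <- files
  })
  invisible(dir)
}

#' Generate scored data whose pertinency follows a known quadratic
#'
#' Builds a null annotation structure (no planted enrichment), scores it,
#' and assigns each protein a known-target label by a Bernoulli draw with
#' success probability `c2 x^2 + c1 x + c0` evaluated at the protein's
#' priority score. The planted coefficients are returned as the recovery
#' truth, so a subsequent [fitPertinencyModel()] can be tested against
#' them.
#'
#' @param coefficients numeric length 3, `(c2, c1, c0)`.
#' @param seed integer seed.
#' @param ... configuration overrides as in [simulateInputs()]
#'   (`coreEnrichment` is forced to 1).
#' @return list with `scored` (data.frame from [scoreDiseases()]), `labels`
#'   (data.frame as from [labelKnownTargets()]) and `truth` (the planted
#'   coefficients).
#' @export
simulateCalibrationTruth <- function(coefficients, seed = 1L, ...) {
  stopifnot(length(coefficients) == 3L)
  cfg <- .simConfig(...)
  cfg$coreEnrichment <- 1
  .withSeed(seed, {
    structure <- .simulateStructure(cfg)
    ann <- annotationTable(structure$annotations[
      c("protein_id", "function_type", "function_id")])
    datasets <- assembleDatasets(data.frame(
      disease_id = structure$membership$disease_id,
      protein_id = structure$membership$protein_id,
      source = "synthetic", stringsAsFactors = FALSE))
    scored <- scoreDiseases(datasets, ann)
    prob <- coefficients[1L] * scored$priority^2 +
      coefficients[2L] * scored$priority + coefficients[3L]
    if (any(prob < 0 | prob > 1))
      stop("quadratic escapes [0, 1] on the realized score range [",
           signif(min(scored$priority), 3), ", ",
           signif(max(scored$priority), 3), "]")
    labels <- data.frame(disease_id = scored$disease_id,
                         protein_id = scored$protein_id,
                         positive = stats::runif(nrow(scored)) < prob,
                         stringsAsFactors = FALSE)
    list(scored = scored, labels = labels,
         truth = c(c2 = coefficients[1L], c1 = coefficients[2L],
                   c0 = coefficients[3L]))
  })
}
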