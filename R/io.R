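## Normalized TSV readers. One schema per table, UTF-8, '#' comment lines,
## no quoting (fields may not contain tabs). Parsed line by line so that a
## malformed row can be reported with its line number.

.readTsv <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    out <- as.data.frame(setNames(rep(list(character()), length(columns)),
                                  columns), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(columns))) {
    bad <- which(nf != length(columns))[1L]
    stop(sprintf("%s: line %d has %d fields, expected %d",
                 path, idx[bad], nf[bad], length(columns)))
  }
  mat <- matrix(unlist(parts, use.names = FALSE),
                ncol = length(columns), byrow = TRUE)
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- columns
  out
}

.checkDoid <- function(ids, context) {
  bad <- unique(ids[!grepl("^DOID:[0-9]+$", ids)])
  if (length(bad))
    stop(context, ": malformed disease id(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(ids)
}

#' Read a protein function-annotation table
#'
#' Reads a three-column TSV (`protein_id`, `function_type`, `function_id`;
#' `#` lines are comments, no header) into an [AnnotationTable-class].
#' Duplicate rows collapse, so annotations behave as sets.
#'
#' @param path path to the TSV file.
#' @param catalog the [FunctionTypeCatalog-class] to validate types against.
#' @return An [AnnotationTable-class].
#' @export
readAnnotations <- function(path, catalog = defaultCatalog()) {
  df <- .readTsv(path, c("protein_id", "function_type", "function_id"))
  unknown <- setdiff(unique(df$function_type), typeNames(catalog))
  if (length(unknown))
    stop(path, ": unknown function type(s): ",
         paste(unknown, collapse = ", "))
  annotationTable(df, catalog)
}

#' Read a disease-protein association table
#'
#' Three columns: `disease_id` (DOID), `protein_id`, `source`. Exact
#' duplicate rows are dropped; the same (disease, protein) pair may appear
#' under several sources and is unioned at assembly.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `disease_id`, `protein_id`, `source`.
#' @export
readDiseaseProteins <- function(path) {
  df <- .readTsv(path, c("disease_id", "protein_id", "source"))
  if (nrow(df)) {
    .checkDoid(df$disease_id, path)
    if (any(!nzchar(df$protein_id)))
      stop(path, ": empty protein id")
    df <- unique(df)
    rownames(df) <- NULL
  }
  df
}

#' Read a drug-target table
#'
#' Two columns: `drug_id`, `protein_id`; de-duplicated on load.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `drug_id`, `protein_id`.
#' @export
readDrugTargets <- function(path) {
  df <- .readTsv(path, c("drug_id", "protein_id"))
  if (nrow(df)) {
    if (any(!nzchar(df$drug_id)) || any(!nzchar(df$protein_id)))
      stop(path, ": empty drug or protein id")
    df <- unique(df)
    rownames(df) <- NULL
  }
  df
}

#' Read a drug-indication table
#'
#' Five columns: `drug_id`, `drug_name`, `indication_code` (prefixed
#' `ICD9CM:` or `ICD10CM:`), `phase` (0-4), `withdrawn` (0/1). Phase-4,
#' non-withdrawn records are the ones that can make a medication eligible
#' for a disease.
#'
#' @param path path to the TSV file.
#' @return data.frame with `phase` integer and `withdrawn` logical.
#' @export
readDrugIndications <- function(path) {
  df <- .readTsv(path, c("drug_id", "drug_name", "indication_code",
                         "phase", "withdrawn"))
  if (nrow(df)) {
    ok <- grepl("^ICD(9|10)CM:.+$", df$indication_code)
    if (any(!ok))
      stop(path, ": indication codes must carry an ICD9CM:/ICD10CM: prefix; ",
           "first offender: ", df$indication_code[!ok][1L])
    phase <- suppressWarnings(as.integer(df$phase))
    if (any(is.na(phase)) || any(phase < 0L | phase > 4L))
      stop(path, ": phase must be an integer in 0..4")
    df$phase <- phase
    df$withdrawn <- df$withdrawn %in% c("1", "TRUE", "true")
  } else {
    df$phase <- integer()
    df$withdrawn <- logical()
  }
  df
}

#' Extract ICD-to-DOID cross-references from a Disease Ontology OBO file
#'
#' Scans `[Term]` stanzas for `id: DOID:...` and `xref: ICD9CM:...` /
#' `xref: ICD10CM:...` lines and returns the inverse map from each ICD code
#' to the set of DOIDs whose stanzas carry it. Obsolete terms are skipped.
#' This is xref extraction only; no ontology-graph reasoning is done.
#'
#' @param path path to an OBO 1.2/1.4 file.
#' @return named list: ICD code (with dialect prefix) -> character vector of
#'   DOIDs.
#' @export
readDoOboXrefs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  starts <- which(trimws(lines) == "[Term]")
  if (!length(starts)) {
    warning(path, ": no [Term] stanza found")
    return(structure(list(), names = character()))
  }
  bounds <- c(starts, length(lines) + 1L)
  codes <- character()
  doids <- character()
  for (i in seq_along(starts)) {
    stanza <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    stanza <- stanza[seq_len(
      if (any(grepl("^\\[", stanza))) which(grepl("^\\[", stanza))[1L] - 1L
      else length(stanza))]
    id <- sub("^id:\\s*", "", grep("^id:\\s*DOID:", stanza, value = TRUE))
    if (length(id) != 1L) next
    if (any(grepl("^is_obsolete:\\s*true", stanza))) next
    xr <- grep("^xref:\\s*ICD(9|10)CM:", stanza, value = TRUE)
    if (!length(xr)) next
    xr <- sub("^xref:\\s*", "", xr)
    xr <- sub("\\s.*$", "", xr)   # trailing xref descriptions
    codes <- c(codes, xr)
    doids <- c(doids, rep(id, length(xr)))
  }
  out <- lapply(split(doids, codes), function(v) sort(unique(v)))
  out[order(names(out))]
}

.SCORED_COLUMNS <- c("disease_id", "protein_id", "priority",
                     "predicted_pertinency", "known_target")

.formatNum <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- ""
  out
}

#' Write a scored protein table
#'
#' Writes one row per (disease, protein) with the final priority score, the
#' predicted pertinency (blank when no calibration model was applied), and
#' the known-target flag. Output is deterministic: fixed column order,
#' floats at 6 decimals, rows sorted by disease, then descending priority,
#' then protein id, so identical inputs produce byte-identical files.
#'
#' @param rows data.frame with columns `disease_id`, `protein_id`,
#'   `priority`, and optionally `predicted_pertinency` and `known_target`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeScoredTable <- function(rows, path) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (!all(c("disease_id", "protein_id", "priority") %in% names(rows)))
    stop("rows must carry disease_id, protein_id and priority")
  if (is.null(rows$predicted_pertinency))
    rows$predicted_pertinency <- NA_real_
  if (is.null(rows$known_target)) rows$known_target <- NA
  ord <- order(rows$disease_id, -rows$priority, rows$protein_id,
               method = "radix")
  rows <- rows[ord, , drop = FALSE]
  body <- paste(rows$disease_id, rows$protein_id,
                .formatNum(rows$priority),
                .formatNum(rows$predicted_pertinency),
                ifelse(is.na(rows$known_target), "",
                       as.character(as.integer(rows$known_target))),
                sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(.SCORED_COLUMNS, collapse = "\t"), body), con,
             sep = "\n")
  invisible(path)
}

#' Read back a scored protein table
#'
#' Inverse of [writeScoredTable()]; used for round-trips and snapshot
#' comparisons.
#'
#' @param path path written by [writeScoredTable()].
#' @return data.frame with typed columns.
#' @export
readScoredTable <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  names(df) <- .SCORED_COLUMNS
  df$priority <- as.numeric(df$priority)
  df$predicted_pertinency <- suppressWarnings(
    as.numeric(ifelse(nzchar(df$predicted_pertinency),
                      df$predicted_pertinency, NA)))
  df$known_target <- ifelse(nzchar(df$known_target),
                            df$known_target == "1", NA)
  df
}

.writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste0("#", paste(names(df), collapse = "\t"))
  body <- if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                         sep = "\t")) else character()
  writeLines(c(comment, header, body), con, sep = "\n")
  invisible(path)
}
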