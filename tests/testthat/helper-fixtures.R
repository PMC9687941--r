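# Shared micro-fixtures, built in code.

# Three proteins, one type: A {f1,f2}, B {f1}, C {f3}.
# mu = {f1:2, f2:1, f3:1}; raw A=3 B=2 C=1; eta = sqrt(9+9); beta = 4/3.
oneTypeCatalog <- function() functionTypeCatalog("uniprot_keyword")

abcAnnotations <- function() {
  annotationTable(data.frame(
    protein_id = c("A", "A", "B", "C"),
    function_type = "uniprot_keyword",
    function_id = c("f1", "f2", "f1", "f3"),
    stringsAsFactors = FALSE), oneTypeCatalog())
}

abcDataset <- function() proteinDiseaseDataset("DOID:1", c("A", "B", "C"))

# Independent brute-force oracle: materialize the binary presence matrix
# rho (proteins x functions) over the dataset's proteins, mu = colSums,
# raw score = rho %*% mu.
bruteForceRaw <- function(proteins, annList) {
  funs <- sort(unique(unlist(annList[proteins], use.names = FALSE)))
  rho <- sapply(funs, function(f)
    vapply(proteins, function(p) f %in% annList[[p]], logical(1)))
  rho <- matrix(as.numeric(rho), nrow = length(proteins),
                dimnames = list(proteins, funs))
  mu <- colSums(rho)
  drop(rho %*% mu)
}

# Random one-type micro-dataset: n proteins, function ids drawn from a
# vocabulary of size v, each protein carrying 0..m functions.
randomMicroDataset <- function(n = NULL, v = 15, m = 6) {
  if (is.null(n)) n <- sample(2:10, 1)
  proteins <- sprintf("P%02d", seq_len(n))
  annList <- lapply(proteins, function(p) {
    k <- sample(0:m, 1)
    unique(sample(sprintf("f%02d", seq_len(v)), k))
  })
  names(annList) <- proteins
  if (!sum(lengths(annList)))   # keep at least one annotated protein
    annList[[1]] <- "f01"
  long <- data.frame(
    protein_id = rep(proteins, lengths(annList)),
    function_type = "uniprot_keyword",
    function_id = unlist(annList, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(proteins = proteins, annList = annList,
       ann = annotationTable(long, oneTypeCatalog()),
       dataset = proteinDiseaseDataset("DOID:9", proteins))
}

writeLinesBin <- function(lines, path) {
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  path
}

# Closed-form weighted least-squares oracle for y ~ 1 + x + x^2.
wlsOracle <- function(x, y, w) {
  X <- cbind(1, x, x^2)
  solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1]
}
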