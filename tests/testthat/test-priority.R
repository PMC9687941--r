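# Worked micro-example: A {f1,f2}, B {f1}, C {f3} in one type.
# mu = {f1:2, f2:1, f3:1}; raw A=3, B=2, C=1; p=3, a=3;
# eta = sqrt(18) = 4.242641; beta = 4/3; norm(A) = 3/(eta*beta) = 0.530330.

test_that("frequency index counts dataset proteins per function", {
  idx <- buildFrequencyIndex(abcDataset(), abcAnnotations())
  mu <- idx$byType$uniprot_keyword$mu
  expect_equal(mu[c("f1", "f2", "f3")], c(f1 = 2L, f2 = 1L, f3 = 1L))
  expect_equal(idx$byType$uniprot_keyword$a, 3L)
  expect_equal(idx$p, 3L)

  # functions of proteins outside the dataset are ignored
  extra <- annotationTable(rbind(
    annotations(abcAnnotations()),
    data.frame(protein_id = "ZZ", function_type = "uniprot_keyword",
               function_id = "f1")), oneTypeCatalog())
  idx2 <- buildFrequencyIndex(abcDataset(), extra)
  expect_equal(idx2$byType$uniprot_keyword$mu[["f1"]], 2L)

  # singleton dataset: all counts 1
  one <- proteinDiseaseDataset("DOID:2", "A")
  idx3 <- buildFrequencyIndex(one, abcAnnotations())
  expect_equal(unname(idx3$byType$uniprot_keyword$mu), c(1L, 1L))
})

test_that("raw priority equals the explicit rho-mu dot product", {
  idx <- buildFrequencyIndex(abcDataset(), abcAnnotations())
  expect_equal(rawPriority("A", idx, abcDataset(), abcAnnotations(),
                           "uniprot_keyword"), 3L)
  expect_equal(rawPriority("B", idx, abcDataset(), abcAnnotations(),
                           "uniprot_keyword"), 2L)
  expect_equal(rawPriority("C", idx, abcDataset(), abcAnnotations(),
                           "uniprot_keyword"), 1L)
  expect_error(rawPriority("ZZ", idx, abcDataset(), abcAnnotations(),
                           "uniprot_keyword"), "not in dataset")

  # unannotated protein scores 0
  ds <- proteinDiseaseDataset("DOID:1", c("A", "B", "C", "D"))
  idx4 <- buildFrequencyIndex(ds, abcAnnotations())
  expect_equal(rawPriority("D", idx4, ds, abcAnnotations(),
                           "uniprot_keyword"), 0L)
})

test_that("normalization factors follow the quadrature and mean-count forms", {
  nf <- normalizationFactors(abcDataset(), abcAnnotations())
  expect_equal(nf$eta, sqrt(18), tolerance = 1e-12)
  expect_equal(nf$eta, 4.242641, tolerance = 1e-6)
  expect_equal(nf$beta, 4 / 3, tolerance = 1e-12)

  # a type with no annotations: a = 0, eta = p, beta = 0
  cat2 <- functionTypeCatalog(c("uniprot_keyword", "interpro"))
  ann2 <- annotationTable(annotations(abcAnnotations()), cat2)
  nf2 <- normalizationFactors(abcDataset(), ann2)
  ip <- nf2[nf2$function_type == "interpro", ]
  expect_equal(ip$a, 0L)
  expect_equal(ip$eta, 3)
  expect_equal(ip$beta, 0)
})

test_that("normalized priority divides by eta * beta and rejects beta 0", {
  expect_equal(normalizedPriority(3, sqrt(18), 4 / 3), 0.530330,
               tolerance = 1e-5)
  expect_equal(normalizedPriority(2, sqrt(18), 4 / 3), 0.353553,
               tolerance = 1e-5)
  expect_equal(normalizedPriority(0, 5, 2), 0)
  expect_error(normalizedPriority(1, 5, 0), "unusable")
  # normalization preserves the raw ranking
  raws <- c(5, 3, 1)
  expect_equal(order(normalizedPriority(raws, sqrt(18), 4 / 3)), order(raws))
})

test_that("final priority averages usable types and handles degenerates", {
  # single usable type: finals equal the normalized scores
  fp <- finalPriority(abcDataset(), abcAnnotations())
  expect_equal(fp$priority[fp$protein_id == "A"], 0.530330,
               tolerance = 1e-6)
  expect_equal(fp$n_types_used, rep(1L, 3))

  # a beta = 0 type drops out of the mean instead of diluting it
  cat2 <- functionTypeCatalog(c("uniprot_keyword", "interpro"))
  ann2 <- annotationTable(annotations(abcAnnotations()), cat2)
  fp2 <- finalPriority(abcDataset(), ann2)
  expect_equal(fp2$priority, fp$priority)
  expect_equal(fp2$n_types_used, rep(1L, 3))

  # two usable types: final is the plain mean of the two normalized scores
  two <- annotationTable(rbind(
    annotations(abcAnnotations()),
    data.frame(protein_id = c("A", "B"), function_type = "interpro",
               function_id = c("i1", "i1"))), cat2)
  fp3 <- finalPriority(abcDataset(), two)
  norm <- attr(fp3, "norm")
  expect_equal(fp3$priority, rowMeans(norm), ignore_attr = TRUE)

  # no usable types: zeros plus a warning
  empty_ds <- proteinDiseaseDataset("DOID:3", c("X", "Y"))
  expect_warning(fp4 <- finalPriority(empty_ds, abcAnnotations()),
                 "no usable")
  expect_equal(fp4$priority, c(0, 0))
})

test_that("dictionary scoring equals the brute-force dot product", {
  set.seed(42)
  for (i in 1:150) {
    md <- randomMicroDataset()
    idx <- buildFrequencyIndex(md$dataset, md$ann)
    oracle <- bruteForceRaw(md$proteins, md$annList)
    for (p in md$proteins)
      expect_identical(
        as.numeric(rawPriority(p, idx, md$dataset, md$ann,
                               "uniprot_keyword")),
        unname(oracle[p]))
  }
})

test_that("adding a shared function strictly increases the raw score", {
  set.seed(7)
  for (i in 1:25) {
    md <- randomMicroDataset(n = 6)
    # pick a function held by someone and a protein not holding it
    held <- unique(unlist(md$annList))
    if (!length(held)) next
    f <- sample(held, 1)
    without <- md$proteins[!vapply(md$annList, function(s) f %in% s,
                                   logical(1))]
    if (!length(without)) next
    x <- without[1]
    idx <- buildFrequencyIndex(md$dataset, md$ann)
    before <- rawPriority(x, idx, md$dataset, md$ann, "uniprot_keyword")
    ann2 <- annotationTable(rbind(
      annotations(md$ann),
      data.frame(protein_id = x, function_type = "uniprot_keyword",
                 function_id = f)), oneTypeCatalog())
    idx2 <- buildFrequencyIndex(md$dataset, ann2)
    after <- rawPriority(x, idx2, md$dataset, ann2, "uniprot_keyword")
    expect_gt(after, before)
  }
})

test_that("k-fold cloning of the annotation pattern preserves the ranking", {
  set.seed(11)
  md <- randomMicroDataset(n = 6)
  fp1 <- suppressWarnings(finalPriority(md$dataset, md$ann))
  k <- 3
  clones <- do.call(rbind, lapply(seq_len(k), function(j) {
    d <- annotations(md$ann)
    d$protein_id <- paste0(d$protein_id, "_c", j)
    d
  }))
  ds_k <- proteinDiseaseDataset("DOID:9",
                                paste0(rep(md$proteins, k), "_c",
                                       rep(seq_len(k), each = 6)))
  fp_k <- suppressWarnings(
    finalPriority(ds_k, annotationTable(clones, oneTypeCatalog())))
  # compare clone j = 1 ranking with the original ranking
  c1 <- fp_k[endsWith(fp_k$protein_id, "_c1"), ]
  c1 <- c1[match(paste0(md$proteins, "_c1"), c1$protein_id), ]
  fp1 <- fp1[match(md$proteins, fp1$protein_id), ]
  expect_equal(rank(c1$priority), rank(fp1$priority))
})

test_that("scores are invariant to protein and annotation input order", {
  set.seed(13)
  md <- randomMicroDataset(n = 8)
  fp1 <- suppressWarnings(finalPriority(md$dataset, md$ann))
  shuf <- annotations(md$ann)[sample(nrow(annotations(md$ann))), ]
  ds2 <- proteinDiseaseDataset("DOID:9", sample(md$proteins))
  fp2 <- suppressWarnings(
    finalPriority(ds2, annotationTable(shuf, oneTypeCatalog())))
  fp2 <- fp2[match(fp1$protein_id, fp2$protein_id), ]
  expect_equal(fp1$priority, fp2$priority, ignore_attr = TRUE)
})
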