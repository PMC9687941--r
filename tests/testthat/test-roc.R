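# Independent oracle: AUC as the fraction of (positive, negative) pairs
# ranked correctly, ties worth half.
pairwiseAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

test_that("three-protein reference cases give AUC 1, 0 and 0.5", {
  s <- c(A = 3, B = 2, C = 1)
  expect_equal(rocAuc(s, c(TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocAuc(s, c(FALSE, FALSE, TRUE))$auc, 0)
  expect_equal(rocAuc(s, c(FALSE, TRUE, FALSE))$auc, 0.5)
  expect_error(rocAuc(s, c(TRUE, TRUE, TRUE), "DOID:5"), "DOID:5")
})

test_that("curve runs (0,0) to (1,1) and its area equals the rank AUC", {
  set.seed(21)
  for (i in 1:300) {
    n <- sample(4:25, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- rocAuc(scores, labels)
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_equal(r$auc, trapezoid(r$curve), tolerance = 1e-12)
    expect_equal(r$auc, pairwiseAuc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms, flips with labels", {
  set.seed(8)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    scores <- stats::rexp(n)
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    a <- rocAuc(scores, labels)$auc
    expect_equal(rocAuc(log1p(scores) * 7 + 2, labels)$auc, a)
    expect_equal(rocAuc(scores, !labels)$auc, 1 - a, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    scores <- round(stats::rnorm(n), 1)
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, quiet = TRUE,
      direction = "<")))
    expect_equal(rocAuc(scores, labels)$auc, ref, tolerance = 1e-10)
  }
})

test_that("mean-AUC summary matches the closed-form t-test", {
  res <- meanAucTtest(c(0.6, 0.7, 0.8))
  expect_equal(res$mean_auc, 0.7)
  expect_equal(res$sd_auc, 0.1)
  tstat <- (0.7 - 0.5) / (0.1 / sqrt(3))        # 3.4641, df 2
  expect_equal(tstat, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * stats::pt(-tstat, df = 2), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  expect_warning(flat <- meanAucTtest(c(0.5, 0.5, 0.5)), "zero variance")
  expect_equal(flat$p_value, 1)
  expect_error(meanAucTtest(0.7), "at least two")
})

test_that("ablation ranks a planted single-type signal above a noise type", {
  set.seed(17)
  cat2 <- functionTypeCatalog(c("uniprot_keyword", "interpro"))
  diseases <- list()
  labels <- list()
  ann_rows <- list()
  for (d in 1:8) {
    prot <- sprintf("D%d_P%02d", d, 1:12)
    pos <- c(rep(TRUE, 4), rep(FALSE, 8))
    # signal type: positives share functions s1..s3; negatives unique ids
    sig <- data.frame(
      protein_id = prot,
      function_type = "uniprot_keyword",
      function_id = c(sample(c("s1", "s2", "s3"), 4, TRUE),
                      sprintf("u%d_%d", d, 5:12)))
    # noise type: everyone gets a random shared-ish id
    noise <- data.frame(
      protein_id = prot,
      function_type = "interpro",
      function_id = sample(sprintf("n%d", 1:6), 12, TRUE))
    ann_rows[[d]] <- rbind(sig, noise)
    diseases[[sprintf("DOID:%d", d)]] <-
      proteinDiseaseDataset(sprintf("DOID:%d", d), prot)
    labels[[d]] <- data.frame(disease_id = sprintf("DOID:%d", d),
                              protein_id = prot, positive = pos)
  }
  ann <- annotationTable(do.call(rbind, ann_rows), cat2)
  labels <- do.call(rbind, labels)
  res <- runAblation(diseases, ann, labels,
                     configs = list(signal = "uniprot_keyword",
                                    noise = "interpro",
                                    all = c("uniprot_keyword", "interpro")))
  expect_gt(res$mean_auc[res$config == "signal"],
            res$mean_auc[res$config == "noise"])
  expect_gt(res$mean_auc[res$config == "signal"], 0.65)

  # a type absent from every dataset yields a flagged empty row
  res2 <- runAblation(diseases, ann, labels,
                      configs = list(absent = "ec_number"))
  expect_true(is.na(res2$mean_auc))
  expect_equal(res2$n_diseases, 0L)
  expect_error(runAblation(diseases, ann, labels, configs = list()),
               "non-empty")
})
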