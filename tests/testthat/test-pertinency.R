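test_that("pertinency is the positive fraction", {
  expect_equal(pertinency(c(rep(TRUE, 2), rep(FALSE, 6))), 0.25)
  expect_equal(pertinency(rep(TRUE, 5)), 1)
  expect_equal(pertinency(rep(FALSE, 3)), 0)
  expect_error(pertinency(logical()), "empty")
})

test_that("fold assignment is balanced, seeded, and validated", {
  ids12 <- sprintf("DOID:%d", 1:12)
  f <- makeFolds(ids12, k = 6, seed = 99)
  expect_equal(sort(unname(table(f))), rep(2L, 6), ignore_attr = TRUE)
  f13 <- makeFolds(sprintf("DOID:%d", 1:13), k = 6, seed = 99)
  expect_equal(sort(unname(table(f13))), c(2L, 2L, 2L, 2L, 2L, 3L),
               ignore_attr = TRUE)
  expect_identical(f, makeFolds(ids12, k = 6, seed = 99))
  expect_false(identical(f, makeFolds(ids12, k = 6, seed = 100)))
  expect_error(makeFolds(ids12[1:4], k = 6), "fewer diseases")
  expect_error(makeFolds(ids12, k = 1), "at least 2 folds")
})

test_that("fold assignment does not disturb the global RNG stream", {
  set.seed(1); a <- stats::runif(1)
  set.seed(1); invisible(makeFolds(sprintf("D%d", 1:10), seed = 5))
  b <- stats::runif(1)
  expect_identical(a, b)
})

makeScored <- function(priorities, diseases) {
  data.frame(disease_id = diseases,
             protein_id = sprintf("P%03d", seq_along(priorities)),
             priority = priorities, stringsAsFactors = FALSE)
}

test_that("binning pools scores, is right-open except the last bin", {
  # scores 0..1; 2 diseases alternating; all positives in the top half
  pri <- seq(0, 1, length.out = 20)
  dis <- rep(c("DOID:1", "DOID:2"), 10)
  scored <- makeScored(pri, dis)
  labels <- data.frame(disease_id = scored$disease_id,
                       protein_id = scored$protein_id,
                       positive = pri > 0.5)
  folds <- c("DOID:1" = 1L, "DOID:2" = 2L)
  st <- binFoldPertinency(scored, labels, folds, kBins = 4)
  expect_equal(nrow(st), 4L)
  expect_equal(st$y, c(0, 0, 1, 1))
  # the max-score protein landed in the last (closed) bin
  expect_equal(sum(st$n_proteins), 20L)
  # mean priority per bin is the mean of the members
  expect_equal(st$x[1], mean(pri[pri < 0.25]))

  # bins empty in every fold are dropped with a warning
  gap <- c(seq(0, 0.2, length.out = 10), 1)
  scored2 <- makeScored(gap, rep(c("DOID:1", "DOID:2"), length.out = 11))
  labels2 <- data.frame(disease_id = scored2$disease_id,
                        protein_id = scored2$protein_id, positive = gap > 0.5)
  expect_warning(st2 <- binFoldPertinency(scored2, labels2, folds,
                                          kBins = 5), "empty in every fold")
  expect_lt(nrow(st2), 5L)
})

test_that("quadratic fit interpolates exact points and honors weights", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  st <- data.frame(bin = 1:6, lo = x - 0.05, hi = x + 0.05,
                   x = x, y = 2 * x^2 + 0.5,
                   variance = rep(1e-4, 6), n_proteins = 10, n_folds = 6)
  m <- fitQuadratic(st)
  co <- modelCoefficients(m)
  expect_equal(unname(co), c(0.5, 0, 2), tolerance = 1e-9)
  expect_equal(fitCorrelation(m), 1, tolerance = 1e-12)

  # matches the closed-form weighted normal-equations solution
  set.seed(2)
  st$y <- st$y + stats::rnorm(6, 0, 0.05)
  st$variance <- stats::runif(6, 1e-4, 1e-2)
  co2 <- modelCoefficients(fitQuadratic(st))
  expect_equal(unname(co2), unname(wlsOracle(st$x, st$y, 1 / st$variance)),
               tolerance = 1e-8)

  # a 10:1 weight pulls the fit toward the heavy point
  st3 <- data.frame(bin = 1:3, lo = 0, hi = 1, x = c(0.1, 0.5, 0.5),
                    y = c(0.1, 0.2, 0.8),
                    variance = c(0.01, 0.01, 0.1),
                    n_proteins = 5, n_folds = 6)
  # two conflicting points at x = 0.5 with weights 100 vs 10: prediction
  # lands nearer the heavily weighted y = 0.2
  m3 <- fitQuadratic(rbind(st3, data.frame(bin = 4, lo = 0, hi = 1,
                                           x = 0.3, y = 0.15,
                                           variance = 0.01,
                                           n_proteins = 5, n_folds = 6)))
  pred <- predictPertinency(m3, 0.5)
  expect_lt(abs(pred - 0.2), abs(pred - 0.8))

  expect_error(fitQuadratic(st[1:2, ]), "at least 3")
  st_col <- st; st_col$x <- 0.3
  expect_error(fitQuadratic(st_col), "collinear")
})

test_that("zero-variance bins borrow the smallest nonzero variance", {
  x <- c(0.1, 0.3, 0.5, 0.7)
  st <- data.frame(bin = 1:4, lo = x - 0.1, hi = x + 0.1, x = x,
                   y = c(0.05, 0.1, 0.3, 0.6),
                   variance = c(0, 1e-3, 4e-3, NA),
                   n_proteins = 8, n_folds = 6)
  m <- fitQuadratic(st)
  w <- 1 / c(1e-3, 1e-3, 4e-3, 1e-3)  # substitution rule
  expect_equal(unname(modelCoefficients(m)),
               unname(wlsOracle(st$x, st$y, w)), tolerance = 1e-8)
})

test_that("prediction evaluates the polynomial and clamps to [0, 1]", {
  m <- pertinencyModel(0.015, -0.110, 1.399)
  expect_equal(predictPertinency(m, 0), 0.015)
  expect_equal(predictPertinency(m, 0.5), 1.399 * 0.25 - 0.110 * 0.5 + 0.015,
               tolerance = 1e-12)
  # a curve whose unclamped minimum is negative clamps to 0
  neg <- pertinencyModel(-0.05, 0, 1)
  expect_equal(predictPertinency(neg, 0.1), 0)
  expect_equal(predictPertinency(pertinencyModel(0.5, 0, 2), 0.5), 1)
  expect_error(predictPertinency(m, -0.1), "non-negative")
})

test_that("r is 1 exactly when the observed points lie on the curve", {
  x <- seq(0.1, 0.6, 0.1)
  on_curve <- data.frame(bin = 1:6, lo = 0, hi = 1, x = x,
                         y = 1.2 * x^2 - 0.1 * x + 0.02,
                         variance = 1e-4, n_proteins = 5, n_folds = 6)
  expect_equal(fitCorrelation(fitQuadratic(on_curve)), 1, tolerance = 1e-12)
  off <- on_curve; off$y[3] <- off$y[3] + 0.1
  expect_lt(fitCorrelation(fitQuadratic(off)), 1)
})

test_that("model JSON round-trips", {
  m <- pertinencyModel(0.02, -0.1, 1.4, r = 0.99,
                       binEdges = seq(0, 0.6, 0.1), foldSeed = 7L,
                       kFolds = 6L)
  p <- withr::local_tempfile(fileext = ".json")
  writeModelJson(m, p)
  back <- readModelJson(p)
  expect_equal(modelCoefficients(back), modelCoefficients(m))
  expect_equal(fitCorrelation(back), 0.99)
  expect_equal(back@binEdges, m@binEdges)
  expect_equal(back@foldSeed, 7L)
})

test_that("labels drawn from a known quadratic are recovered by the fit", {
  truth <- c(0, 0, 0.3)   # c2, c1, c0
  sim <- simulateCalibrationTruth(truth, seed = 4, nDiseases = 30)
  folds <- makeFolds(unique(sim$scored$disease_id), seed = 4)
  st <- binFoldPertinency(sim$scored, sim$labels, folds)
  m <- fitQuadratic(st)
  # flat truth: predictions inside the observed score range sit near 0.3
  # (outside that narrow range a quadratic extrapolates freely, so only
  # in-range behavior is meaningful)
  xs <- stats::quantile(sim$scored$priority, c(0.1, 0.5, 0.9))
  pred <- predictPertinency(m, xs)
  expect_true(all(abs(pred - 0.3) < 0.1))
  key <- paste(sim$labels$disease_id, sim$labels$protein_id)
  expect_equal(mean(sim$labels$positive), 0.3, tolerance = 0.05)

  none <- simulateCalibrationTruth(c(0, 0, 0), seed = 4, nDiseases = 5)
  expect_false(any(none$labels$positive))
})
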