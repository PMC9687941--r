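## Priority -> pertinency calibration: pool the scores of all validation
## diseases, cut the score range into equal-width bins, estimate each bin's
## pertinency (fraction of known targets) on k random disease folds, and fit
## a weighted quadratic through the bin means with weight 1/variance.

.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Pertinency score of a labeled protein set
#'
#' The fraction of the set's proteins that are known targets of medications
#' already indicated for the disease -- the empirical success rate the
#' calibration model predicts.
#'
#' @param positive logical vector of known-target labels (non-empty).
#' @return a value in `[0, 1]`.
#' @examples
#' pertinency(c(TRUE, TRUE, rep(FALSE, 6)))  # 0.25
#' @export
pertinency <- function(positive) {
  if (!length(positive)) stop("pertinency undefined for an empty set")
  mean(as.logical(positive))
}

#' Partition diseases into cross-validation folds
#'
#' Seeded uniform random partition into `k` folds whose sizes differ by at
#' most one; folds are by disease, not by protein, so a disease's proteins
#' never straddle folds.
#'
#' @param diseaseIds character vector of disease ids (at least `k`).
#' @param k number of folds (default 6).
#' @param seed integer seed; the same seed always yields the same partition.
#' @return named integer vector: disease id -> fold in `1..k`.
#' @export
makeFolds <- function(diseaseIds, k = 6L, seed = 1L) {
  diseaseIds <- unique(as.character(diseaseIds))
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds (fold variance is undefined for 1)")
  if (length(diseaseIds) < k)
    stop("fewer diseases (", length(diseaseIds), ") than folds (", k, ")")
  fold <- integer(length(diseaseIds))
  .withSeed(seed, {
    fold[sample.int(length(diseaseIds))] <-
      rep_len(seq_len(k), length(diseaseIds))
  })
  names(fold) <- diseaseIds
  fold
}

#' Bin pooled priority scores and estimate per-bin, per-fold pertinency
#'
#' Scores of all validation diseases are pooled and the full score range is
#' cut into `kBins` equal-width intervals (right-open except the last, so
#' the maximum score is binned). For every bin and fold, the pertinency is
#' computed over the proteins of that fold's diseases falling in the bin;
#' each bin is then summarized by the mean priority of all its members, the
#' mean of the fold pertinencies, and their variance across folds.
#'
#' @param scored data.frame from [scoreDiseases()].
#' @param labels data.frame from [labelKnownTargets()].
#' @param folds named integer vector from [makeFolds()]; only diseases
#'   present here contribute.
#' @param kBins number of score bins (default 6).
#' @return data.frame with columns `bin`, `lo`, `hi`, `x` (mean priority),
#'   `y` (mean pertinency), `variance`, `n_proteins`, `n_folds`; bins empty
#'   in every fold are dropped with a warning. Attributes `edges` and
#'   `k_folds` record the binning and fold count.
#' @export
binFoldPertinency <- function(scored, labels, folds, kBins = 6L) {
  kBins <- as.integer(kBins)
  if (kBins < 1L) stop("kBins must be >= 1")
  df <- scored[scored$disease_id %in% names(folds), , drop = FALSE]
  if (!nrow(df)) stop("no scored proteins for the diseases in 'folds'")
  key <- paste(labels$disease_id, labels$protein_id)
  df$positive <- labels$positive[match(paste(df$disease_id, df$protein_id),
                                       key)]
  if (anyNA(df$positive)) stop("labels missing for some scored proteins")
  df$fold <- folds[df$disease_id]
  k_folds <- max(folds)

  rng <- range(df$priority)
  if (diff(rng) <= 0) stop("all priority scores identical; cannot bin")
  edges <- seq(rng[1L], rng[2L], length.out = kBins + 1L)
  df$bin <- findInterval(df$priority, edges, rightmost.closed = TRUE)

  rows <- lapply(seq_len(kBins), function(b) {
    mem <- df[df$bin == b, , drop = FALSE]
    if (!nrow(mem)) return(NULL)
    pert <- vapply(seq_len(k_folds), function(f) {
      inf <- mem$positive[mem$fold == f]
      if (length(inf)) pertinency(inf) else NA_real_
    }, numeric(1))
    pert <- pert[!is.na(pert)]
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1L],
               x = mean(mem$priority), y = mean(pert),
               variance = if (length(pert) >= 2L) stats::var(pert)
                          else NA_real_,
               n_proteins = nrow(mem), n_folds = length(pert))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped)
    warning(dropped, " bin(s) empty in every fold; dropped from the fit")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "edges") <- edges
  attr(out, "k_folds") <- k_folds
  out
}

#' Fit the weighted quadratic pertinency model
#'
#' Weighted least squares of bin pertinency on bin mean priority with a
#' second-degree polynomial; each bin is weighted by the inverse of its
#' across-fold variance. A bin with zero (or undefined) variance borrows
#' the smallest nonzero variance among the bins so that no weight is
#' infinite; when no bin has positive variance all weights are equal.
#'
#' @param stats data.frame from [binFoldPertinency()] (at least 3 bins with
#'   distinct mean priorities).
#' @param foldSeed integer recorded in the model for provenance.
#' @return A [PertinencyModel-class]; its `r` is the Pearson correlation
#'   between observed and fitted bin pertinencies.
#' @export
fitQuadratic <- function(stats, foldSeed = NA_integer_) {
  if (nrow(stats) < 3L)
    stop("need at least 3 bins to fit a quadratic; got ", nrow(stats))
  if (length(unique(stats$x)) < 3L)
    stop("bin mean priorities are collinear; quadratic fit undetermined")
  v <- stats$variance
  v[is.na(v)] <- 0
  if (any(v > 0)) v[v <= 0] <- min(v[v > 0]) else v[] <- 1
  w <- 1 / v
  fit <- stats::lm(y ~ x + I(x^2), data = stats, weights = w)
  co <- stats::coef(fit)
  r <- stats::cor(stats$y, stats::fitted(fit))
  edges <- attr(stats, "edges")
  pertinencyModel(c0 = unname(co[1L]), c1 = unname(co[2L]),
                  c2 = unname(co[3L]), r = r,
                  binEdges = if (is.null(edges)) numeric() else edges,
                  foldSeed = foldSeed,
                  kFolds = attr(stats, "k_folds"))
}

#' Predict pertinency from priority scores
#'
#' Evaluates the fitted quadratic and clamps the result into `[0, 1]`
#' (pertinency is a proportion).
#'
#' @param model a [PertinencyModel-class].
#' @param priority numeric vector of non-negative priority scores.
#' @return numeric vector of predicted pertinencies in `[0, 1]`.
#' @export
predictPertinency <- function(model, priority) {
  if (any(priority < 0))
    stop("priority scores are non-negative by construction")
  co <- modelCoefficients(model)
  y <- co[["c2"]] * priority^2 + co[["c1"]] * priority + co[["c0"]]
  pmin(1, pmax(0, y))
}

#' Fit the calibration end to end
#'
#' Convenience wrapper chaining [makeFolds()], [binFoldPertinency()] and
#' [fitQuadratic()].
#'
#' @param scored data.frame from [scoreDiseases()] restricted to validation
#'   diseases.
#' @param labels data.frame from [labelKnownTargets()].
#' @param kBins,kFolds bin and fold counts (defaults 6 and 6).
#' @param seed fold-assignment seed.
#' @return A [PertinencyModel-class].
#' @export
fitPertinencyModel <- function(scored, labels, kBins = 6L, kFolds = 6L,
                               seed = 1L) {
  folds <- makeFolds(unique(scored$disease_id), k = kFolds, seed = seed)
  stats <- binFoldPertinency(scored, labels, folds, kBins = kBins)
  fitQuadratic(stats, foldSeed = as.integer(seed))
}

#' Write / read a pertinency model as JSON
#'
#' @param model a [PertinencyModel-class].
#' @param path output path (`model.json`).
#' @return the path (write) or the model (read).
#' @export
writeModelJson <- function(model, path) {
  co <- modelCoefficients(model)
  obj <- list(c2 = co[["c2"]], c1 = co[["c1"]], c0 = co[["c0"]],
              r = fitCorrelation(model), bin_edges = model@binEdges,
              fold_seed = model@foldSeed, k_bins = max(
                0L, length(model@binEdges) - 1L),
              k_folds = model@kFolds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pertinencyModel(c0 = obj$c0, c1 = obj$c1, c2 = obj$c2, r = obj$r,
                  binEdges = if (is.null(obj$bin_edges)) numeric()
                             else obj$bin_edges,
                  foldSeed = if (is.null(obj$fold_seed)) NA_integer_
                             else obj$fold_seed,
                  kFolds = if (is.null(obj$k_folds)) NA_integer_
                           else obj$k_folds)
}
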