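#' Downsample the cells of one tissue
#'
#' Uniformly samples `roundHalfUp(ratio * n)` of the tissue's cells without
#' replacement (half-up rounding, fixed for determinism); other tissues are
#' untouched and the original cell order is preserved.
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param tissue tissue name present in `tissueLabel(x)`.
#' @param ratio retention ratio in (0, 1\].
#' @param seed integer seed.
#' @return the downsampled [AnnotatedCounts-class].
#' @export
downsampleTissue <- function(x, tissue, ratio, seed = 1) {
  stopifnot(ratio > 0, ratio <= 1)
  ti <- tissueLabel(x)
  idx <- which(ti == tissue)
  if (length(idx) == 0) stop("tissue '", tissue, "' not present")
  m <- roundHalfUp(ratio * length(idx))
  if (m == 0) stop("downsampling would retain 0 cells")
  set.seed(seed)
  keep <- sort(sample(idx, m))
  x[, sort(c(setdiff(seq_len(ncol(x)), idx), keep))]
}

#' Imbalanced tissue-mixture experiment
#'
#' Emulates classification of mixed samples with imbalanced tissue
#' proportions: per trial, a mixture is assembled by sampling
#' `roundHalfUp(ratio_t * cellsPerTissue)` cells of each tissue from a
#' held-out pool, predicted with a classifier trained once on the (clean)
#' reference, and evaluated at the cell-type level. The mixture is a batch
#' of independently scored cells, so its accuracy is the cell-weighted
#' accuracy of its tissue strata.
#'
#' @param reference a labeled, quality-controlled [AnnotatedCounts-class]
#'   used for training (ignored when `model` is supplied).
#' @param pool a labeled [AnnotatedCounts-class], disjoint from the
#'   reference, with at least `cellsPerTissue` cells per tissue.
#' @param ratios numeric vector of per-tissue mixture ratios in (0, 1\],
#'   one per tissue; named by tissue, or matched to `sort(unique(tissues))`.
#' @param cellsPerTissue nominal cells per tissue before downsampling
#'   (default 3000).
#' @param trials random repeats (default 10).
#' @param seed integer seed.
#' @param model optional pre-trained [CellTypeModel-class].
#' @param C,tol SVM hyperparameters when training here.
#' @return one-row data.frame: `ratios`, `total_cells`, and trial-averaged
#'   `accuracy`, `ari`, `mf1`, `nmi`.
#' @export
runMixtureExperiment <- function(reference, pool, ratios,
                                 cellsPerTissue = 3000, trials = 10,
                                 seed = 1, model = NULL, C = 1.0,
                                 tol = 1e-4) {
  tissues <- sort(unique(tissueLabel(pool)))
  if (is.null(names(ratios))) {
    stopifnot(length(ratios) == length(tissues))
    names(ratios) <- tissues
  }
  stopifnot(all(ratios > 0), all(ratios <= 1),
            all(names(ratios) %in% tissues))
  if (!is.null(reference) &&
      length(intersect(cellIds(reference), cellIds(pool))))
    stop("reference and pool share cell ids")
  poolTi <- tissueLabel(pool)
  for (t in names(ratios))
    if (sum(poolTi == t) < cellsPerTissue)
      stop("pool has fewer than ", cellsPerTissue, " cells for tissue '",
           t, "'")
  if (is.null(model))
    model <- trainClassifier(logTransform(reference), C = C, tol = tol,
                             seed = seed)
  map <- typeTissueMap(pool)
  take <- roundHalfUp(ratios * cellsPerTissue)
  totalCells <- sum(take)
  poolLp <- logTransform(pool)
  seeds <- .subSeeds(seed, trials)
  mets <- matrix(NA_real_, trials, 4,
                 dimnames = list(NULL, c("accuracy", "ari", "mf1", "nmi")))
  for (tr in seq_len(trials)) {
    set.seed(seeds[tr])
    idx <- unlist(lapply(names(ratios), function(t) {
      cand <- which(poolTi == t)
      sample(sample(cand, cellsPerTissue), take[[t]])
    }))
    sub <- poolLp[, sort(idx)]
    pr <- predictCells(model, sub, map)
    rep <- evaluateLabels(cellType(sub), predictedType(pr))
    m <- reportMetrics(rep)
    mets[tr, ] <- c(m[["accuracy"]], m[["ari"]], m[["medianF1"]],
                    m[["nmi"]])
  }
  data.frame(ratios = paste(ratios[names(ratios)], collapse = ":"),
             total_cells = totalCells,
             accuracy = mean(mets[, "accuracy"]), ari = mean(mets[, "ari"]),
             mf1 = mean(mets[, "mf1"]), nmi = mean(mets[, "nmi"]),
             stringsAsFactors = FALSE)
}

#' Randomly drop out genes
#'
#' Globally samples `roundHalfUp((1 - dropoutRatio) * nGenes)` genes to
#' retain (uniformly, without replacement) and restricts all cells to them;
#' cell count and labels are untouched. A dropout ratio of 0.99 therefore
#' retains 1% of genes. Per-cell binomial count thinning is available as an
#' alternative dropout model via `mode = "counts"`, where each transcript
#' is kept independently with probability `1 - dropoutRatio`.
#'
#' @param x an [AnnotatedCounts-class].
#' @param dropoutRatio fraction of genes dropped, in \[0, 1).
#' @param seed integer seed.
#' @param mode `"genes"` (default, global gene removal) or `"counts"`
#'   (binomial count thinning).
#' @return the reduced [AnnotatedCounts-class].
#' @export
applyGeneDropout <- function(x, dropoutRatio, seed = 1,
                             mode = c("genes", "counts")) {
  mode <- match.arg(mode)
  stopifnot(dropoutRatio >= 0, dropoutRatio < 1)
  if (dropoutRatio == 0) return(x)
  set.seed(seed)
  if (mode == "genes") {
    nKeep <- roundHalfUp((1 - dropoutRatio) * nrow(x))
    if (nKeep == 0) stop("dropout would retain 0 genes")
    keep <- sort(sample.int(nrow(x), nKeep))
    x[keep, ]
  } else {
    counts <- methods::as(SummarizedExperiment::assay(x, "counts"),
                          "CsparseMatrix")
    counts@x <- as.numeric(stats::rbinom(length(counts@x), counts@x,
                                         1 - dropoutRatio))
    SummarizedExperiment::assay(x, "counts") <- Matrix::drop0(counts)
    if ("log1p" %in% SummarizedExperiment::assayNames(x))
      x <- logTransform(x)
    x
  }
}

#' Gene-dropout robustness experiment
#'
#' Trains the classifier once on the reference (quality-filtered first when
#' `withQC`), then for every dropout ratio and trial removes a random gene
#' subset from the query, predicts the surviving profile and evaluates
#' cell-type calls. The trial standard deviation quantifies the rising
#' instability at extreme dropout.
#'
#' @param reference a labeled [AnnotatedCounts-class] (training data).
#' @param query a labeled [AnnotatedCounts-class] to degrade and classify.
#' @param dropoutRatios numeric vector in \[0, 1).
#' @param trials random repeats per ratio (default 10).
#' @param seed integer seed.
#' @param withQC apply [fitReclassifier()] + [filterByQuality()] to the
#'   reference before training (default FALSE).
#' @param threshold quality threshold when `withQC` (default 0.8).
#' @param C,tol SVM hyperparameters.
#' @return data.frame with one row per ratio: mean and sd over trials of
#'   accuracy, ari, nmi.
#' @export
runDropoutExperiment <- function(reference, query, dropoutRatios,
                                 trials = 10, seed = 1, withQC = FALSE,
                                 threshold = 0.8, C = 1.0, tol = 1e-4) {
  stopifnot(all(dropoutRatios >= 0), all(dropoutRatios < 1))
  reference <- logTransform(reference)
  if (withQC)
    reference <- qcReference(reference, threshold = threshold, C = C,
                             tol = tol, seed = seed)$clean
  model <- trainClassifier(reference, C = C, tol = tol, seed = seed)
  map <- typeTissueMap(query)
  query <- logTransform(query)
  seeds <- .subSeeds(seed, trials * length(dropoutRatios))
  rows <- vector("list", length(dropoutRatios))
  for (ri in seq_along(dropoutRatios)) {
    mets <- matrix(NA_real_, trials, 3,
                   dimnames = list(NULL, c("accuracy", "ari", "nmi")))
    for (tr in seq_len(trials)) {
      q <- applyGeneDropout(query, dropoutRatios[ri],
                            seed = seeds[(ri - 1) * trials + tr])
      pr <- predictCells(model, q, map)
      m <- reportMetrics(evaluateLabels(cellType(q), predictedType(pr)))
      mets[tr, ] <- m[c("accuracy", "ari", "nmi")]
    }
    rows[[ri]] <- data.frame(
      dropout_ratio = dropoutRatios[ri],
      accuracy_mean = mean(mets[, "accuracy"]),
      accuracy_sd = stats::sd(mets[, "accuracy"]),
      ari_mean = mean(mets[, "ari"]), ari_sd = stats::sd(mets[, "ari"]),
      nmi_mean = mean(mets[, "nmi"]), nmi_sd = stats::sd(mets[, "nmi"]))
  }
  do.call(rbind, rows)
}
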