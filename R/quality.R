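#' Per-cell quality scores from a reclassification model
#'
#' Scores every cell against every class of the model: decision score
#' \eqn{s_c = \omega_c^\top \phi(x) + b_c}, quality probability
#' \eqn{P_c = 1/(1+\exp(A_c s_c + B_c))}. `maxProb` is the per-cell maximum
#' probability over classes (the quality score thresholded downstream) and
#' `reclassifiedLabel` the argmax-probability class. When `labels` are
#' supplied (or present on `x`), `assignedProb` records each cell's
#' probability under its assigned label.
#'
#' @param model a [CellTypeModel-class].
#' @param x an [AnnotatedCounts-class]; genes are matched to the model by
#'   exact id on the intersection.
#' @param labels optional per-cell assigned labels.
#' @return a [QualityScores-class].
#' @export
qualityScores <- function(model, x, labels = cellType(x)) {
  sp <- .modelScores(model, .logProfile(x))
  p <- sp$prob
  maxP <- apply(p, 1, max)
  lab <- colnames(p)[max.col(p, ties.method = "first")]
  assigned <- rep(NA_real_, nrow(p))
  if (!is.null(labels)) {
    idx <- match(as.character(labels), colnames(p))
    ok <- !is.na(idx)
    assigned[ok] <- p[cbind(which(ok), idx[ok])]
  }
  methods::new("QualityScores", cellIds = cellIds(x), prob = p,
               maxProb = unname(maxP), reclassifiedLabel = lab,
               assignedProb = assigned)
}

#' @rdname accessors
#' @export
setMethod("cellIds", "QualityScores", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("classProb", "QualityScores", function(x) x@prob)
#' @rdname accessors
#' @export
setMethod("maxProb", "QualityScores", function(x) x@maxProb)
#' @rdname accessors
#' @export
setMethod("reclassifiedLabel", "QualityScores", function(x) x@reclassifiedLabel)
#' @rdname accessors
#' @export
setMethod("assignedProb", "QualityScores", function(x) x@assignedProb)

setMethod("show", "QualityScores", function(object) {
  cat("QualityScores:", length(object@cellIds), "cells x",
      ncol(object@prob), "classes\n")
  if (length(object@maxProb))
    cat(sprintf("  maxProb median %.3f, fraction >= 0.8: %.3f\n",
                stats::median(object@maxProb), mean(object@maxProb >= 0.8)))
})

#' Out-of-fold quality scores for a reference
#'
#' The default quality-differentiation path. Reference cells are scored by
#' models that did not train on them: cells are split into stratified
#' folds, a one-vs-rest linear SVM is fitted on each fold's complement, and
#' every cell receives the decision scores of its held-out model. Per-class
#' Platt calibrations are then fitted on these out-of-fold scores. Scoring
#' a training point with its own in-sample model overstates confidence
#' whenever the gene count is comparable to the cell count (the soft margin
#' partially memorizes noisy cells), which masks exactly the doublets,
#' contaminated and mislabeled cells the quality score exists to expose;
#' out-of-fold scoring restores honest probabilities (see the vignette).
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param labels per-cell class labels (default `cellType(x)`); every class
#'   needs at least `folds` cells.
#' @param C,tol SVM hyperparameters.
#' @param seed integer seed (folds and fits).
#' @param folds number of cross-fit folds (default 5).
#' @return a [QualityScores-class] with out-of-fold probabilities.
#' @export
crossFitQualityScores <- function(x, labels = cellType(x), C = 1.0,
                                  tol = 1e-4, seed = 1, folds = 5) {
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(x))
  lp <- .logProfile(x)
  classes <- sort(unique(labels))
  fold <- .stratifiedFolds(labels, folds, seed)
  seeds <- .subSeeds(seed + 1L, folds)
  s <- matrix(NA_real_, ncol(x), length(classes),
              dimnames = list(cellIds(x), classes))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (!any(!tr)) next
    raw <- .fitOVRraw(lp[, tr, drop = FALSE], labels[tr], C, tol, seeds[f])
    sf <- as.matrix(Matrix::crossprod(lp[, !tr, drop = FALSE], raw$W))
    sf <- sweep(sf, 2, raw$biases, "+")
    s[!tr, raw$classes] <- sf
  }
  if (anyNA(s))
    stop("some classes were absent from a training fold; reduce `folds`")
  p <- s
  for (ci in seq_along(classes)) {
    ab <- .plattCalibrate(s[, ci], labels == classes[ci])
    p[, ci] <- 1 / (1 + exp(ab["A"] * s[, ci] + ab["B"]))
  }
  maxP <- apply(p, 1, max)
  lab <- colnames(p)[max.col(p, ties.method = "first")]
  assigned <- p[cbind(seq_len(nrow(p)), match(labels, colnames(p)))]
  rownames(p) <- NULL
  methods::new("QualityScores", cellIds = cellIds(x), prob = p,
               maxProb = unname(maxP), reclassifiedLabel = lab,
               assignedProb = unname(assigned))
}

#' One-call reference quality control
#'
#' Phase 2 in one step: out-of-fold quality scores via
#' [crossFitQualityScores()], then [filterByQuality()] at `threshold`.
#'
#' @inheritParams crossFitQualityScores
#' @inheritParams filterByQuality
#' @return list with `clean`, `noisy` ([AnnotatedCounts-class]) and
#'   `scores` ([QualityScores-class]).
#' @export
qcReference <- function(x, labels = cellType(x), threshold = 0.8, C = 1.0,
                        tol = 1e-4, seed = 1, folds = 5,
                        score = c("max", "assigned")) {
  qs <- crossFitQualityScores(x, labels, C = C, tol = tol, seed = seed,
                              folds = folds)
  out <- filterByQuality(x, qs, threshold, score = match.arg(score))
  out$scores <- qs
  out
}

#' Retain high-confidence reference cells
#'
#' Splits a labeled dataset into `clean` (cells with quality score at least
#' `threshold`, inclusive) and `noisy` (the rest); the two parts partition
#' the input and preserve cell order. By default the thresholded score is
#' `maxProb`; `score = "assigned"` instead thresholds the probability of
#' each cell's own assigned label, which additionally flags cells whose
#' reclassification disagrees with their label (see the vignette).
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param qs a [QualityScores-class] covering all cells of `x`.
#' @param threshold retention threshold in \[0, 1\] (default 0.8).
#' @param score `"max"` (default) or `"assigned"`.
#' @return list with elements `clean` and `noisy`, both
#'   [AnnotatedCounts-class].
#' @export
filterByQuality <- function(x, qs, threshold = 0.8,
                            score = c("max", "assigned")) {
  score <- match.arg(score)
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  idx <- match(cellIds(x), cellIds(qs))
  if (anyNA(idx))
    stop("quality scores missing for cell '",
         cellIds(x)[which(is.na(idx))[1]], "'")
  s <- switch(score, max = maxProb(qs)[idx], assigned = {
    a <- assignedProb(qs)[idx]
    if (anyNA(a)) stop("assigned-label probabilities are not available")
    a
  })
  keep <- s >= threshold
  list(clean = x[, keep], noisy = x[, !keep])
}
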