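# stratified fold assignment: within each class, shuffled cells are dealt
# cyclically across folds, so fold sizes per class differ by at most one
.stratifiedFolds <- function(labels, k, seed) {
  if (k < 2) stop("k must be at least 2")
  sizes <- table(labels)
  if (any(sizes < k))
    warning("class '", names(sizes)[which(sizes < k)[1]],
            "' has fewer than ", k, " cells; stratification degrades")
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of the linear SVM classifier
#'
#' Splits cells into `k` folds stratified by cell type, fits the classifier
#' on each training portion and evaluates on the held-out fold. Classes
#' absent from a fold's training portion cannot be predicted there and
#' score recall 0 for that fold.
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param k number of folds (default 10).
#' @param C,tol SVM hyperparameters.
#' @param seed integer seed fixing fold membership and fits.
#' @param labels per-cell class labels (default `cellType(x)`).
#' @return list with `mean` (named numeric: fold-averaged accuracy, ari,
#'   nmi, medianF1, meanF1), `folds` (per-fold [EvaluationReport-class]
#'   list) and `foldAssignments`.
#' @export
crossValidate <- function(x, k = 10, C = 1.0, tol = 1e-4, seed = 1,
                          labels = cellType(x)) {
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(x))
  folds <- .stratifiedFolds(labels, k, seed)
  x <- logTransform(x)
  seeds <- .subSeeds(seed + 1L, k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- folds != f
    if (!any(trIdx) || !any(!trIdx)) next
    model <- .fitOVR(.logProfile(x)[, trIdx, drop = FALSE],
                     labels[trIdx], C, tol, seeds[f])
    sp <- .modelScores(model, .logProfile(x)[, !trIdx, drop = FALSE])
    pred <- colnames(sp$scores)[max.col(sp$scores, ties.method = "first")]
    reports[[f]] <- evaluateLabels(labels[!trIdx], pred)
  }
  reports <- Filter(Negate(is.null), reports)
  means <- rowMeans(vapply(reports, reportMetrics, numeric(5)))
  list(mean = means, folds = reports, foldAssignments = folds)
}

#' Hyperparameter grid search by cross-validation
#'
#' Runs [crossValidate()] at every (C, tol) combination and returns the
#' full table (no silent best-only reduction).
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param C,tol numeric vectors spanning the grid.
#' @inheritParams crossValidate
#' @return data.frame with one row per grid point: C, tol, accuracy, ari,
#'   nmi, medianF1.
#' @export
gridSearch <- function(x, C = c(0.1, 1, 10), tol = c(1e-3, 1e-4), k = 10,
                       seed = 1, labels = cellType(x)) {
  grid <- expand.grid(C = C, tol = tol, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty grid")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- crossValidate(x, k = k, C = grid$C[i], tol = grid$tol[i],
                        seed = seed, labels = labels)
    data.frame(C = grid$C[i], tol = grid$tol[i],
               accuracy = cv$mean[["accuracy"]], ari = cv$mean[["ari"]],
               nmi = cv$mean[["nmi"]], medianF1 = cv$mean[["medianF1"]])
  })
  do.call(rbind, rows)
}
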