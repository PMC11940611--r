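#' Predict cell types and tissues for query cells
#'
#' Scores each query cell independently against every model class
#' (\eqn{s_c = \omega_c^\top \phi(x) + b_c}), assigns the argmax-score class
#' (the closest cell type), and maps it to a tissue through
#' `celltypeToTissue`. Calibrated probabilities accompany the calls; an
#' optional `rejectBelow` threshold relabels low-confidence cells
#' `"unassigned"` (off by default: every query cell is assigned).
#'
#' @param model a [CellTypeModel-class].
#' @param query an [AnnotatedCounts-class]; genes matched by exact id on
#'   the intersection with the model's training genes.
#' @param celltypeToTissue named character vector (or data.frame with
#'   columns `cell_type`, `tissue`) mapping every model class to a tissue.
#' @param rejectBelow optional probability threshold below which the
#'   predicted type and tissue are set to `"unassigned"` (default `NULL`).
#' @return a [PredictionResult-class].
#' @export
predictCells <- function(model, query, celltypeToTissue,
                         rejectBelow = NULL) {
  if (is.data.frame(celltypeToTissue))
    celltypeToTissue <- setNames(as.character(celltypeToTissue$tissue),
                                 celltypeToTissue$cell_type)
  missing <- setdiff(model@classes, names(celltypeToTissue))
  if (length(missing))
    stop("no tissue mapped for class '", missing[1], "'")
  sp <- .modelScores(model, .logProfile(query))
  ptype <- colnames(sp$scores)[max.col(sp$scores, ties.method = "first")]
  ptissue <- unname(celltypeToTissue[ptype])
  maxP <- apply(sp$prob, 1, max)
  res <- methods::new("PredictionResult", cellIds = cellIds(query),
                      scores = sp$scores, prob = sp$prob,
                      predictedType = ptype, predictedTissue = ptissue,
                      maxProb = unname(maxP),
                      classTissue = celltypeToTissue[model@classes])
  if (!is.null(rejectBelow)) {
    rej <- res@maxProb < rejectBelow
    res@predictedType[rej] <- "unassigned"
    res@predictedTissue[rej] <- "unassigned"
    res@classTissue <- c(res@classTissue, unassigned = "unassigned")
  }
  methods::validObject(res)
  res
}

#' @rdname accessors
#' @export
setMethod("cellIds", "PredictionResult", function(x) x@cellIds)
#' @rdname accessors
#' @export
setMethod("classProb", "PredictionResult", function(x) x@prob)
#' @rdname accessors
#' @export
setMethod("maxProb", "PredictionResult", function(x) x@maxProb)
#' @rdname accessors
#' @export
setMethod("decisionScores", "PredictionResult", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("predictedType", "PredictionResult", function(x) x@predictedType)
#' @rdname accessors
#' @export
setMethod("predictedTissue", "PredictionResult", function(x) x@predictedTissue)

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", length(object@cellIds), "cells,",
      ncol(object@scores), "classes\n")
  tab <- sort(table(object@predictedTissue), decreasing = TRUE)
  cat("  tissues:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
})

#' @export
#' @method as.data.frame PredictionResult
as.data.frame.PredictionResult <- function(x, ...) {
  data.frame(cell_id = x@cellIds, predicted_cell_type = x@predictedType,
             predicted_tissue = x@predictedTissue, max_prob = x@maxProb,
             stringsAsFactors = FALSE)
}

#' Consolidate per-cell predictions into a tissue composition
#'
#' Tallies predicted tissues over all cells into counts and proportions.
#'
#' @param pr a [PredictionResult-class].
#' @return data.frame with columns `tissue`, `n_cells`, `proportion`
#'   (proportions sum to 1 when any cell is present); zero rows for an
#'   empty prediction.
#' @export
consolidateTissue <- function(pr) {
  n <- length(pr@cellIds)
  if (n == 0)
    return(data.frame(tissue = character(), n_cells = integer(),
                      proportion = numeric()))
  tab <- table(pr@predictedTissue)
  data.frame(tissue = names(tab), n_cells = as.integer(tab),
             proportion = as.numeric(tab) / n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Likelihood ratio of two candidate tissues
#'
#' For each cell, LR = (highest calibrated probability among `tissueA`'s
#' classes) / (highest among `tissueB`'s classes), with both numerator and
#' denominator floored at `floor` to keep ratios finite. The aggregate over
#' cells assumes inter-cell independence and is reported as the sum of
#' per-cell log10 LRs. This aggregation is this package's interpretation of
#' tissue-level evidence; no canonical formula exists.
#'
#' @param pr a [PredictionResult-class].
#' @param tissueA,tissueB tissue names present in the class-tissue map.
#' @param floor probability floor (default 1e-6).
#' @return list with `perCell` (numeric LR per cell) and `log10Aggregate`.
#' @export
tissueLikelihoodRatio <- function(pr, tissueA, tissueB, floor = 1e-6) {
  for (t in c(tissueA, tissueB))
    if (!t %in% pr@classTissue)
      stop("unknown tissue '", t, "'")
  pA <- .tissueMaxProb(pr, tissueA, floor)
  pB <- .tissueMaxProb(pr, tissueB, floor)
  lr <- pA / pB
  list(perCell = setNames(lr, pr@cellIds),
       log10Aggregate = sum(log10(lr)))
}

.tissueMaxProb <- function(pr, tissue, floor) {
  cls <- names(pr@classTissue)[pr@classTissue == tissue]
  cls <- intersect(cls, colnames(pr@prob))
  p <- apply(pr@prob[, cls, drop = FALSE], 1, max)
  pmax(p, floor)
}
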