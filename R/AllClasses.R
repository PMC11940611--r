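#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' AnnotatedCounts: a labeled single-cell count matrix
#'
#' Thin extension of [SingleCellExperiment::SingleCellExperiment] holding a
#' raw transcript count matrix (genes as rows, cells as columns, the
#' Bioconductor convention) together with optional per-cell `cell_type`,
#' `tissue` and `donor` annotations in `colData`. Validity enforces the data
#' model: a `"counts"` assay of non-negative integral values, unique gene and
#' cell identifiers, and a many-to-one cell-type-to-tissue mapping.
#'
#' @slot int_elementMetadata,int_colData,... inherited from
#'   `SingleCellExperiment`.
#' @seealso [AnnotatedCounts()] the constructor; [filterCells()],
#'   [logTransform()], [readCounts()].
#' @export
setClass("AnnotatedCounts", contains = "SingleCellExperiment")

setValidity("AnnotatedCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(vals) && any(vals < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(vals) && any(vals != floor(vals)))
    msg <- c(msg, "counts must be integral")
  if (nrow(object) && (is.null(rownames(object)) ||
                       anyDuplicated(rownames(object))))
    msg <- c(msg, "gene ids must be present and unique")
  if (ncol(object) && (is.null(colnames(object)) ||
                       anyDuplicated(colnames(object))))
    msg <- c(msg, "cell ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (all(c("cell_type", "tissue") %in% colnames(cd))) {
    map <- unique(data.frame(ct = cd$cell_type, ti = cd$tissue))
    if (anyDuplicated(map$ct))
      msg <- c(msg, "each cell type must map to exactly one tissue")
  }
  for (lab in intersect(c("cell_type", "tissue", "donor"), colnames(cd)))
    if (length(cd[[lab]]) != ncol(object))
      msg <- c(msg, sprintf("label '%s' must have one entry per cell", lab))
  if (length(msg)) msg else TRUE
})

#' CellTypeModel: one-vs-rest linear SVM with per-class Platt calibration
#'
#' Holds, for each cell-type class, the linear decision function
#' \eqn{s_c(x) = \omega_c^\top \phi(x) + b_c} fitted on natural-log
#' transformed expression \eqn{\phi(x) = \ln(1 + x)}, and the logistic
#' calibration pair \eqn{(A_c, B_c)} mapping decision scores to quality
#' probabilities \eqn{P_c = 1/(1 + \exp(A_c s + B_c))} with \eqn{A_c < 0} so
#' that probability increases with the margin.
#'
#' @slot classes ordered character vector of cell-type labels.
#' @slot geneIds genes the model was trained on (rows of `weights`).
#' @slot weights numeric matrix, genes x classes.
#' @slot biases,calibA,calibB per-class numerics.
#' @slot C,tol hyperparameters of the soft-margin fit.
#' @export
setClass("CellTypeModel",
  representation(classes = "character", geneIds = "character",
    weights = "matrix", biases = "numeric", calibA = "numeric",
    calibB = "numeric", C = "numeric", tol = "numeric"),
  prototype(weights = matrix(0, 0, 0), C = 1, tol = 1e-4))

setValidity("CellTypeModel", function(object) {
  k <- length(object@classes)
  msg <- character()
  if (anyDuplicated(object@classes)) msg <- c(msg, "duplicate classes")
  if (ncol(object@weights) != k || length(object@biases) != k ||
      length(object@calibA) != k || length(object@calibB) != k)
    msg <- c(msg, "one (weights, bias, A, B) tuple per class is required")
  if (nrow(object@weights) != length(object@geneIds))
    msg <- c(msg, "weights must have one row per training gene")
  if (any(object@calibA >= 0))
    msg <- c(msg, "calibration slope A must be negative for every class")
  if (length(msg)) msg else TRUE
})

#' QualityScores: per-cell reclassification probabilities
#'
#' Per-cell, per-class quality probabilities from a [CellTypeModel-class], the
#' per-cell maximum probability, and the reclassified (argmax-probability)
#' label. `maxProb` is the paper-style quality score thresholded by
#' [filterByQuality()].
#'
#' @slot cellIds character.
#' @slot prob numeric matrix, cells x classes, entries in \[0, 1\].
#' @slot assignedProb probability of each cell's assigned training label
#'   (NA-filled when scores were computed without labels).
#' @export
setClass("QualityScores",
  representation(cellIds = "character", prob = "matrix",
    maxProb = "numeric", reclassifiedLabel = "character",
    assignedProb = "numeric"))

setValidity("QualityScores", function(object) {
  n <- length(object@cellIds)
  msg <- character()
  if (nrow(object@prob) != n || length(object@maxProb) != n ||
      length(object@reclassifiedLabel) != n)
    msg <- c(msg, "per-cell fields must have one entry per cell")
  if (n) {
    if (any(object@prob < 0 | object@prob > 1))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    rm <- apply(object@prob, 1, max)
    if (any(abs(rm - object@maxProb) > 1e-8))
      msg <- c(msg, "maxProb must equal the per-cell maximum probability")
    am <- colnames(object@prob)[max.col(object@prob, ties.method = "first")]
    if (!all(object@reclassifiedLabel == am))
      msg <- c(msg, "reclassifiedLabel must be the argmax-probability class")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionResult: query-cell class and tissue calls
#'
#' Per-cell decision scores and calibrated probabilities under a
#' [CellTypeModel-class], the argmax-score cell-type call, and the tissue mapped
#' from that call.
#'
#' @slot scores,prob numeric matrices, cells x classes.
#' @slot classTissue named character: tissue of every model class.
#' @export
setClass("PredictionResult",
  representation(cellIds = "character", scores = "matrix", prob = "matrix",
    predictedType = "character", predictedTissue = "character",
    maxProb = "numeric", classTissue = "character"))

setValidity("PredictionResult", function(object) {
  n <- length(object@cellIds)
  msg <- character()
  if (nrow(object@scores) != n || nrow(object@prob) != n ||
      length(object@predictedType) != n || length(object@predictedTissue) != n)
    msg <- c(msg, "per-cell fields must have one entry per cell")
  if (n) {
    am <- colnames(object@scores)[max.col(object@scores, ties.method = "first")]
    rej <- object@predictedType == "unassigned"  # optional reject threshold
    if (!all(object@predictedType[!rej] == am[!rej]))
      msg <- c(msg, "predictedType must be the argmax-score class")
    if (!all(object@predictedTissue[!rej] ==
             unname(object@classTissue[object@predictedType[!rej]])))
      msg <- c(msg, "predictedTissue must be the mapped tissue of predictedType")
  }
  if (!all(colnames(object@scores) %in% names(object@classTissue)))
    msg <- c(msg, "classTissue must cover all model classes")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: classification and clustering agreement metrics
#'
#' @slot accuracy exact-match fraction.
#' @slot ari adjusted Rand index (pair-counting, chance-corrected).
#' @slot nmi normalized mutual information (arithmetic-mean normalization).
#' @slot medianF1 median over true classes of per-class F1 ("MF1").
#' @slot meanF1 mean over true classes of per-class F1 (reported alongside
#'   MF1 because both summaries circulate under similar names).
#' @slot perClass data.frame with class, precision, recall, f1, support.
#' @export
setClass("EvaluationReport",
  representation(accuracy = "numeric", ari = "numeric", nmi = "numeric",
    medianF1 = "numeric", meanF1 = "numeric", perClass = "data.frame",
    nCells = "integer"))
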