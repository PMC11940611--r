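#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two labelings, from the
#' contingency-table form of the adjusted formula. Invariant to label
#' renaming on either side; 1 for identical partitions.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
ariScore <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- length(a)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)  # both partitions trivial
  (sumIJ - expected) / (maxIdx - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two labelings normalized by the arithmetic
#' mean of their entropies (natural log); 0/0 (two single-cluster
#' labelings) is defined as 0. Symmetric and in \[0, 1\].
#'
#' @inheritParams ariScore
#' @return NMI in \[0, 1\].
#' @export
nmiScore <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

#' Evaluate predicted against true labels
#'
#' Computes accuracy (exact-match fraction), adjusted Rand index,
#' normalized mutual information, per-class one-vs-rest precision, recall
#' and F1 (0/0 defined as 0) over the true classes, and their median
#' ("MF1") and mean summaries.
#'
#' @param trueLabels,predictedLabels equal-length label vectors.
#' @return an [EvaluationReport-class].
#' @export
evaluateLabels <- function(trueLabels, predictedLabels) {
  trueLabels <- as.character(trueLabels)
  predictedLabels <- as.character(predictedLabels)
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must have equal length")
  if (length(trueLabels) == 0) stop("empty label vectors")
  classes <- sort(unique(trueLabels))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(trueLabels == cl & predictedLabels == cl)
    fp <- sum(trueLabels != cl & predictedLabels == cl)
    fn <- sum(trueLabels == cl & predictedLabels != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(trueLabels == cl), stringsAsFactors = FALSE)
  }))
  methods::new("EvaluationReport",
    accuracy = mean(trueLabels == predictedLabels),
    ari = ariScore(trueLabels, predictedLabels),
    nmi = nmiScore(trueLabels, predictedLabels),
    medianF1 = stats::median(per$f1), meanF1 = mean(per$f1),
    perClass = per, nCells = length(trueLabels))
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf(
    "EvaluationReport (%d cells): accuracy %.4f, ARI %.4f, NMI %.4f, MF1 %.4f\n",
    object@nCells, object@accuracy, object@ari, object@nmi,
    object@medianF1))
})

#' @export
#' @method as.data.frame EvaluationReport
as.data.frame.EvaluationReport <- function(x, ...) x@perClass

#' Scalar metrics of an EvaluationReport
#' @param report an [EvaluationReport-class].
#' @return named numeric: accuracy, ari, nmi, medianF1, meanF1.
#' @export
reportMetrics <- function(report) {
  c(accuracy = report@accuracy, ari = report@ari, nmi = report@nmi,
    medianF1 = report@medianF1, meanF1 = report@meanF1)
}
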