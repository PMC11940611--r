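# log-likelihood of a zero/positive mixture from sufficient statistics:
# n0 zeros, npos positive log-values with sum s1 and sum of squares s2.
# pi is the zero probability; positives are Normal(mu, sigma) with the
# maximum-likelihood plug-in and a variance floor guarding degenerate
# (constant or single-observation) positive sets.
.bimodLik <- function(n0, npos, s1, s2, varFloor = 0.05) {
  n <- n0 + npos
  ll <- 0
  if (is.matrix(n0)) stop("internal: scalar stats expected")
  piHat <- n0 / n
  if (n0 > 0) ll <- ll + n0 * log(piHat)
  if (npos > 0) {
    ll <- ll + npos * log(1 - piHat)
    mu <- s1 / npos
    ss <- max(s2 - s1^2 / npos, 0)
    sig2 <- max(ss / npos, varFloor)
    ll <- ll - npos / 2 * log(2 * pi * sig2) - ss / (2 * sig2)
  }
  ll
}

#' Rank marker genes by a bimodal likelihood-ratio test
#'
#' For every gene and every cell type (class vs all other cells), models the
#' natural-log expression as a zero/positive mixture: zero with probability
#' \eqn{\pi}, else Normal(\eqn{\mu}, \eqn{\sigma}) on the positive log
#' values. The alternative fits (\eqn{\pi}, \eqn{\mu}, \eqn{\sigma}) per
#' group; the null shares one set; the statistic \eqn{2(\ell_1 - \ell_0)}
#' is referred to a chi-square with 3 degrees of freedom (the free-parameter
#' difference). The effect size is the log fold-change of average
#' expression, `ae_logfc` \eqn{= \ln(\bar e_{in} + 1) - \ln(\bar e_{out} +
#' 1)} with \eqn{\bar e} the group mean of \eqn{e^{v} - 1} on log values
#' \eqn{v}. Within each class, genes are ranked 1..m by ascending p-value,
#' ties broken by descending `ae_logfc`, then lexicographic gene id.
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param labels per-cell class labels (default `cellType(x)`).
#' @param varFloor variance floor (natural-log expression scale) for the
#'   positive component (default 0.05). Low discrete counts make positive
#'   log values nearly constant, and an unbounded ML variance would let the
#'   Normal density diverge; the floor caps its contribution at a realistic
#'   technical-noise level. Groups with all-zero expression contribute
#'   through the zero component only.
#' @return data.frame (the marker table) with columns `gene_id`,
#'   `cell_type`, `p_value`, `ae_logfc`, `rank`.
#' @export
rankMarkers <- function(x, labels = cellType(x), varFloor = 0.05) {
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(x))
  classes <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes < 3))
    stop("class '", names(sizes)[which(sizes < 3)[1]],
         "' has fewer than 3 cells")
  lp <- .logProfile(x)
  lp2 <- lp; if (methods::is(lp2, "sparseMatrix")) lp2@x <- lp2@x^2 else lp2 <- lp2^2
  em <- lp; if (methods::is(em, "sparseMatrix")) em@x <- expm1(em@x) else em <- expm1(em)
  totN <- ncol(lp)
  totNnz <- Matrix::rowSums(lp > 0)
  totS1 <- Matrix::rowSums(lp)
  totS2 <- Matrix::rowSums(lp2)
  totE <- Matrix::rowSums(em)
  out <- vector("list", length(classes))
  for (ci in seq_along(classes)) {
    inCls <- labels == classes[ci]
    n1 <- sum(inCls)
    nnzIn <- Matrix::rowSums(lp[, inCls, drop = FALSE] > 0)
    s1In <- Matrix::rowSums(lp[, inCls, drop = FALSE])
    s2In <- Matrix::rowSums(lp2[, inCls, drop = FALSE])
    eIn <- Matrix::rowSums(em[, inCls, drop = FALSE])
    n2 <- totN - n1
    nnzOut <- totNnz - nnzIn; s1Out <- totS1 - s1In; s2Out <- totS2 - s2In
    lr <- numeric(nrow(lp))
    for (g in seq_len(nrow(lp))) {
      llIn <- .bimodLik(n1 - nnzIn[g], nnzIn[g], s1In[g], s2In[g], varFloor)
      llOut <- .bimodLik(n2 - nnzOut[g], nnzOut[g], s1Out[g], s2Out[g],
                         varFloor)
      llNull <- .bimodLik(totN - totNnz[g], totNnz[g], totS1[g], totS2[g],
                          varFloor)
      lr[g] <- max(2 * (llIn + llOut - llNull), 0)
    }
    p <- stats::pchisq(lr, df = 3, lower.tail = FALSE)
    fc <- log1p(eIn / n1) - log1p((totE - eIn) / n2)
    ord <- order(p, -fc, rownames(lp))
    rk <- integer(nrow(lp)); rk[ord] <- seq_len(nrow(lp))
    out[[ci]] <- data.frame(gene_id = rownames(lp),
                            cell_type = classes[ci], p_value = p,
                            ae_logfc = fc, rank = rk,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select top-ranked markers per cell type
#'
#' Restricts the marker table to genes with positive `ae_logfc`
#' (up-regulated in the class) and keeps, per class, the `topN` best by the
#' table's rank order. A class may yield fewer than `topN` markers.
#'
#' @param markerTable data.frame from [rankMarkers()].
#' @param topN markers per class (>= 1).
#' @return the subset marker table, ordered by class then rank.
#' @export
selectMarkers <- function(markerTable, topN) {
  stopifnot(topN >= 1)
  elig <- markerTable[markerTable$ae_logfc > 0, , drop = FALSE]
  elig <- elig[order(elig$cell_type, elig$rank), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(elig)), elig$cell_type),
                        function(i) utils::head(i, topN)))
  out <- elig[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify cells by majority vote of marker genes
#'
#' Each class receives one vote per selected marker gene with count > `minCount`
#' in the cell; votes are normalized by the class's marker count (so classes
#' with fewer markers are not penalized; set `normalize = FALSE` for raw
#' counts). The cell is assigned the class with the highest normalized vote;
#' exact ties go to the lexicographically smallest class and are flagged;
#' cells with zero votes everywhere are `"unassigned"`.
#'
#' @param x an [AnnotatedCounts-class].
#' @param markers a (selected) marker table.
#' @param minCount expression threshold for a vote (default 0: any nonzero
#'   count counts as expressed).
#' @param normalize divide votes by the class's marker count (default TRUE).
#' @return data.frame with columns `cell_id`, `predicted_class`, `tie`.
#' @export
mgmvClassify <- function(x, markers, minCount = 0, normalize = TRUE) {
  if (nrow(markers) == 0) stop("empty marker table")
  classes <- sort(unique(markers$cell_type))
  counts <- SummarizedExperiment::assay(x, "counts")
  votes <- matrix(0, ncol(counts), length(classes),
                  dimnames = list(colnames(counts), classes))
  for (ci in seq_along(classes)) {
    genes <- intersect(markers$gene_id[markers$cell_type == classes[ci]],
                       rownames(counts))
    if (length(genes) == 0) next
    v <- Matrix::colSums(counts[genes, , drop = FALSE] > minCount)
    votes[, ci] <- if (normalize) v / length(genes) else v
  }
  best <- apply(votes, 1, max)
  pred <- character(nrow(votes)); tie <- logical(nrow(votes))
  for (i in seq_len(nrow(votes))) {
    if (best[i] == 0) { pred[i] <- "unassigned"; next }
    winners <- classes[votes[i, ] == best[i]]
    tie[i] <- length(winners) > 1
    pred[i] <- winners[1]  # classes sorted: lexicographically smallest
  }
  data.frame(cell_id = colnames(counts), predicted_class = pred, tie = tie,
             stringsAsFactors = FALSE, row.names = NULL)
}
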