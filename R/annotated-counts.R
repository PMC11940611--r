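#' Construct an AnnotatedCounts object
#'
#' @param counts matrix or sparse Matrix of raw transcript counts, genes as
#'   rows and cells as columns. Row and column names are the gene and cell
#'   identifiers and must be unique; they are taken from `geneIds`/`cellIds`
#'   when supplied.
#' @param cellType,tissue,donor optional per-cell character labels.
#' @param geneIds,cellIds optional identifier vectors overriding dimnames.
#' @return an [AnnotatedCounts-class] object.
#' @examples
#' m <- Matrix::Matrix(c(0, 1, 2, 3), 2, 2, sparse = TRUE,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' ac <- AnnotatedCounts(m, cellType = c("T", "B"),
#'   tissue = c("Blood", "Blood"))
#' ac
#' @export
AnnotatedCounts <- function(counts, cellType = NULL, tissue = NULL,
                            donor = NULL, geneIds = NULL, cellIds = NULL) {
  if (!is.null(geneIds)) rownames(counts) <- geneIds
  if (!is.null(cellIds)) colnames(counts) <- cellIds
  if (!methods::is(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(cellType)) cd$cell_type <- as.character(cellType)
  if (!is.null(tissue)) cd$tissue <- as.character(tissue)
  if (!is.null(donor)) cd$donor <- as.character(donor)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  methods::new("AnnotatedCounts", sce)
}

#' @rdname accessors
#' @export
setMethod("cellIds", "AnnotatedCounts", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("geneIds", "AnnotatedCounts", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("cellType", "AnnotatedCounts",
  function(x) SummarizedExperiment::colData(x)$cell_type)
#' @rdname accessors
#' @export
setMethod("cellType<-", "AnnotatedCounts", function(x, value) {
  SummarizedExperiment::colData(x)$cell_type <- as.character(value)
  methods::validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("tissueLabel", "AnnotatedCounts",
  function(x) SummarizedExperiment::colData(x)$tissue)
#' @rdname accessors
#' @export
setMethod("tissueLabel<-", "AnnotatedCounts", function(x, value) {
  SummarizedExperiment::colData(x)$tissue <- as.character(value)
  methods::validObject(x)
  x
})
#' @rdname accessors
#' @export
setMethod("donorId", "AnnotatedCounts",
  function(x) SummarizedExperiment::colData(x)$donor)

#' @rdname accessors
#' @export
setMethod("typeTissueMap", "AnnotatedCounts", function(x) {
  ct <- cellType(x); ti <- tissueLabel(x)
  if (is.null(ct) || is.null(ti))
    stop("both cell_type and tissue labels are required for a type->tissue map")
  map <- unique(data.frame(ct = ct, ti = ti, stringsAsFactors = FALSE))
  stats::setNames(map$ti, map$ct)
})

setMethod("show", "AnnotatedCounts", function(object) {
  cat("AnnotatedCounts:", nrow(object), "genes x", ncol(object), "cells\n")
  cd <- SummarizedExperiment::colData(object)
  if ("cell_type" %in% colnames(cd))
    cat("  cell types:", length(unique(cd$cell_type)), "\n")
  if ("tissue" %in% colnames(cd))
    cat("  tissues:", length(unique(cd$tissue)), "\n")
  m <- SummarizedExperiment::assay(object, "counts")
  cat(sprintf("  nonzero fraction: %.3f\n",
              Matrix::nnzero(m) / prod(dim(m))))
})

#' Filter cells by captured genes and total transcripts
#'
#' Retains the cells with at least `minGenes` genes detected (count > 0) and
#' at least `minCounts` total transcripts; both bounds are inclusive. The
#' gene set and the cell order are unchanged. Idempotent.
#'
#' @param x an [AnnotatedCounts-class] object.
#' @param minGenes minimum number of genes with nonzero count (default 100).
#' @param minCounts minimum total transcript count (default 1000).
#' @return the filtered [AnnotatedCounts-class] (possibly with 0 cells).
#' @export
filterCells <- function(x, minGenes = 100, minCounts = 1000) {
  stopifnot(minGenes >= 0, minCounts >= 0)
  m <- SummarizedExperiment::assay(x, "counts")
  keep <- Matrix::colSums(m > 0) >= minGenes &
    Matrix::colSums(m) >= minCounts
  x[, keep]
}

#' Natural-log transform of counts
#'
#' Adds (or recomputes) the `"log1p"` assay holding \eqn{\ln(1 + c)} for each
#' count \eqn{c}, the representation on which all model fitting operates.
#' Zeros map to zeros, so the sparsity pattern is preserved.
#'
#' @param x an [AnnotatedCounts-class] object.
#' @return `x` with a `"log1p"` assay.
#' @export
logTransform <- function(x) {
  m <- SummarizedExperiment::assay(x, "counts")
  if (methods::is(m, "sparseMatrix")) {
    lp <- m
    lp@x <- log1p(lp@x)
  } else {
    lp <- log1p(m)
  }
  SummarizedExperiment::assay(x, "log1p") <- lp
  x
}

# genes x cells log1p matrix, computing it on the fly if absent
.logProfile <- function(x) {
  if ("log1p" %in% SummarizedExperiment::assayNames(x))
    return(SummarizedExperiment::assay(x, "log1p"))
  SummarizedExperiment::assay(logTransform(x), "log1p")
}
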