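#' Read a count matrix from disk
#'
#' Two on-disk layouts are supported. `"mtx"` is the 10x convention: a
#' directory holding `matrix.mtx` (Matrix Market coordinate triplets,
#' genes x cells), `features.tsv` (gene ids in the first column) and
#' `barcodes.tsv` (cell ids). `"dense"` is a delimited text table laid out
#' cells x genes: a header row of gene ids and a first column of cell ids;
#' it is transposed into the internal genes x cells orientation on read.
#'
#' @param path for `"mtx"`, the directory holding the three files; for
#'   `"dense"`, the table file.
#' @param format `"mtx"` or `"dense"`.
#' @param sep field separator for `"dense"` (default tab).
#' @return an [AnnotatedCounts-class] object (unlabeled).
#' @export
readCounts <- function(path, format = c("mtx", "dense"), sep = "\t") {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    if (methods::is(m, "nMatrix"))  # pattern file: entries are implicit ones
      m <- methods::as(m, "dMatrix")
    firstField <- function(f)  # robust to empty sidecars (0 genes/cells)
      vapply(strsplit(readLines(f), "\t", fixed = TRUE),
             function(x) x[1], character(1))
    genes <- firstField(feat)
    cells <- firstField(bc)
    if (length(genes) != nrow(m))
      stop("features.tsv lists ", length(genes), " genes but matrix has ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("barcodes.tsv lists ", length(cells), " cells but matrix has ",
           ncol(m), " columns")
    .checkIds(genes, "gene"); .checkIds(cells, "cell")
    m <- methods::as(m, "CsparseMatrix")
    .checkEntries(m, genes, cells)
    dimnames(m) <- list(genes, cells)
    AnnotatedCounts(m)
  } else {
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- t(as.matrix(tab))  # on disk cells x genes -> internal genes x cells
    .checkIds(rownames(m), "gene"); .checkIds(colnames(m), "cell")
    m <- Matrix::Matrix(m, sparse = TRUE)
    .checkEntries(m, rownames(m), colnames(m))
    AnnotatedCounts(m)
  }
}

.checkIds <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate ", what, " id: '", dup, "'")
  }
}

.checkEntries <- function(m, genes, cells) {
  tm <- methods::as(m, "TsparseMatrix")
  bad <- which(tm@x < 0 | tm@x != floor(tm@x))
  if (length(bad)) {
    i <- tm@i[bad[1]] + 1L; j <- tm@j[bad[1]] + 1L
    stop(sprintf(
      "invalid count %g at gene '%s', cell '%s' (must be a non-negative integer)",
      tm@x[bad[1]], genes[i], cells[j]))
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [readCounts()]: `"mtx"` writes `matrix.mtx`, `features.tsv`
#' and `barcodes.tsv` into a directory; `"dense"` writes a cells x genes
#' delimited table with a gene-id header and a leading cell-id column.
#' A written matrix re-reads to an identical object.
#'
#' @param x an [AnnotatedCounts-class] object.
#' @inheritParams readCounts
#' @return invisibly, the path written.
#' @export
writeCounts <- function(x, path, format = c("mtx", "dense"), sep = "\t") {
  format <- match.arg(format)
  m <- SummarizedExperiment::assay(x, "counts")
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(m, "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    utils::write.table(
      data.frame(id = rownames(m), name = rownames(m),
                 type = "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(bc = colnames(m)),
      file.path(path, "barcodes.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else {
    dense <- t(as.matrix(m))
    tab <- data.frame(cell_id = rownames(dense), dense, check.names = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and attach per-cell label tables
#'
#' Label tables are TSV files with columns `cell_id`, `cell_type`, `tissue`
#' and optionally `donor`. `attachLabels` matches rows to the cells of `x`
#' by `cell_id` and fails if any cell is missing from the table.
#'
#' @param path TSV file path.
#' @return `readLabels`: a data.frame. `attachLabels`: the labeled
#'   [AnnotatedCounts-class].
#' @export
readLabels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "cell_type", "tissue")
  if (!all(need %in% colnames(tab)))
    stop("label table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname readLabels
#' @param x an [AnnotatedCounts-class] object.
#' @param labels a data.frame as returned by `readLabels`.
#' @export
attachLabels <- function(x, labels) {
  idx <- match(cellIds(x), labels$cell_id)
  if (anyNA(idx))
    stop("no label row for cell '", cellIds(x)[which(is.na(idx))[1]], "'")
  cd <- SummarizedExperiment::colData(x)
  cd$cell_type <- labels$cell_type[idx]
  cd$tissue <- labels$tissue[idx]
  if ("donor" %in% colnames(labels)) cd$donor <- labels$donor[idx]
  SummarizedExperiment::colData(x) <- cd
  methods::validObject(x)
  x
}

#' @rdname readLabels
#' @export
writeLabels <- function(x, path) {
  tab <- data.frame(cell_id = cellIds(x), cell_type = cellType(x),
                    tissue = tissueLabel(x), stringsAsFactors = FALSE)
  if (!is.null(donorId(x))) tab$donor <- donorId(x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
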