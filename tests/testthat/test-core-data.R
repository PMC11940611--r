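test_that("mtx triplet round-trip is lossless and preserves sparsity", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 4, 3, 1), j = c(1, 1, 2, 3, 3),
                            x = c(2, 1, 7, 3, 5), dims = c(4, 3))
  dimnames(m) <- list(paste0("g", 1:4), paste0("c", 1:3))
  x <- AnnotatedCounts(m)
  dir <- withr::local_tempdir()
  writeCounts(x, dir, format = "mtx")
  y <- readCounts(dir, format = "mtx")
  expect_identical(geneIds(y), geneIds(x))
  expect_identical(cellIds(y), cellIds(x))
  cm <- SummarizedExperiment::assay(y, "counts")
  expect_equal(as.matrix(cm), as.matrix(m))
  expect_equal(Matrix::nnzero(cm), 5)
})

test_that("dense round-trip is lossless and lays out cells x genes on disk", {
  m <- matrix(c(0, 1, 2, 3), 2, 2,
              dimnames = list(c("gA", "gB"), c("c1", "c2")))
  x <- AnnotatedCounts(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCounts(x, f, format = "dense")
  lines <- readLines(f)
  expect_length(lines, 3)  # header + 2 cell rows
  expect_identical(strsplit(lines[1], "\t")[[1]], c("cell_id", "gA", "gB"))
  y <- readCounts(f, format = "dense")
  expect_equal(as.matrix(SummarizedExperiment::assay(y, "counts")), m)
})

test_that("round-trip holds for random fixture matrices in both formats", {
  set.seed(5)
  for (i in 1:3) {
    m <- matrix(rpois(60, 1), 10, 6,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:6)))
    x <- AnnotatedCounts(m)
    dir <- withr::local_tempdir()
    writeCounts(x, dir, format = "mtx")
    expect_equal(as.matrix(SummarizedExperiment::assay(
      readCounts(dir, "mtx"), "counts")), m)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCounts(x, f, format = "dense")
    expect_equal(as.matrix(SummarizedExperiment::assay(
      readCounts(f, "dense"), "counts")), m)
  }
})

test_that("writing an empty matrix yields a valid re-readable file set", {
  m <- Matrix::Matrix(0, 3, 0, sparse = TRUE,
                      dimnames = list(paste0("g", 1:3), character()))
  x <- AnnotatedCounts(m)
  dir <- withr::local_tempdir()
  writeCounts(x, dir, format = "mtx")
  y <- readCounts(dir, format = "mtx")
  expect_equal(ncol(y), 0)
  expect_equal(nrow(y), 3)
})

test_that("invalid entries and identifiers are rejected with a named record", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "2 1 -1"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gB"), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  expect_error(readCounts(dir, "mtx"), "gB.*c1|invalid count")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "2 2 1", "1 2 0.5"), file.path(dir, "matrix.mtx"))
  expect_error(readCounts(dir, "mtx"), "gA.*c2")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 1", "1 1 1"), file.path(dir, "matrix.mtx"))
  writeLines(c("gA", "gA"), file.path(dir, "features.tsv"))
  expect_error(readCounts(dir, "mtx"), "duplicate gene id")
  expect_error(AnnotatedCounts(matrix(-1, 1, 1,
    dimnames = list("g", "c"))), "non-negative")
})

test_that("filterCells applies inclusive gene and count thresholds", {
  # cell A: 99 expressed genes, 2000 total -> removed (gene bound)
  # cell B: exactly 100 expressed genes, exactly 1000 total -> retained
  # cell C: 150 expressed genes, 999 total -> removed (count bound)
  m <- matrix(0L, 200, 3, dimnames = list(sprintf("g%03d", 1:200),
                                          c("A", "B", "C")))
  m[1:99, 1] <- c(rep(20L, 98), 40L)   # 99 genes, 2000 counts
  m[1:100, 2] <- 10L                   # 100 genes, 1000 counts
  m[1:149, 3] <- 6L; m[150, 3] <- 105L # 150 genes, 999 counts
  expect_equal(sum(m[, 1]), 2000)
  expect_equal(sum(m[, 3]), 999)
  x <- AnnotatedCounts(m)
  kept <- filterCells(x)
  expect_identical(cellIds(kept), "B")
  expect_equal(nrow(kept), 200)  # gene set unchanged
  # idempotent
  expect_identical(cellIds(filterCells(kept)), cellIds(kept))
  # all-zero matrix -> nothing retained
  z <- AnnotatedCounts(matrix(0L, 5, 4,
    dimnames = list(paste0("g", 1:5), paste0("c", 1:4))))
  expect_equal(ncol(filterCells(z)), 0)
})

test_that("log transform is ln(1 + count), monotone, sparsity-preserving", {
  set.seed(2)
  m <- matrix(rpois(300, 0.6), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
  x <- logTransform(AnnotatedCounts(m))
  lp <- as.matrix(SummarizedExperiment::assay(x, "log1p"))
  expect_true(all(abs(lp - log(1 + m)) < 1e-12))
  expect_equal(lp[m == 0], rep(0, sum(m == 0)))
  expect_equal(unname(lp[which(m == 1)[1]]), log(2), tolerance = 1e-12)
  ord <- order(m)  # monotone in the count
  expect_true(all(diff(lp[ord]) >= 0))
})

test_that("label tables attach by cell id and enforce coverage", {
  x <- smallRef(1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLabels(x, f)
  tab <- readLabels(f)
  y <- AnnotatedCounts(SummarizedExperiment::assay(x, "counts"))
  y <- attachLabels(y, tab)
  expect_identical(cellType(y), cellType(x))
  expect_identical(tissueLabel(y), tissueLabel(x))
  expect_error(attachLabels(y, tab[-1, ]), "no label row")
})

test_that("the data model rejects inconsistent type-to-tissue maps", {
  m <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(AnnotatedCounts(m, cellType = c("T", "T"),
                               tissue = c("Blood", "Skin")),
               "exactly one tissue")
  ok <- AnnotatedCounts(m, cellType = c("T", "B"),
                        tissue = c("Blood", "Blood"))
  expect_identical(unname(typeTissueMap(ok)["T"]), "Blood")
})
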