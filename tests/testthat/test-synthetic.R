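test_that("generation is bitwise reproducible from the config", {
  cfg <- smallConfig(seed = 33)
  x1 <- generateReference(cfg)
  x2 <- generateReference(cfg)
  expect_equal(SummarizedExperiment::assay(x1, "counts"),
               SummarizedExperiment::assay(x2, "counts"))
  expect_identical(cellType(x1), cellType(x2))
  x3 <- generateReference(smallConfig(seed = 34))
  expect_false(identical(SummarizedExperiment::assay(x1, "counts"),
                         SummarizedExperiment::assay(x3, "counts")))
})

test_that("marker genes carry the configured fold signal; fold 1 carries none", {
  x <- generateReference(generatorConfig(seed = 3))  # full default scale
  cm <- SummarizedExperiment::assay(x, "counts")
  markers <- S4Vectors::metadata(x)$markers
  ct <- cellType(x)
  for (cl in names(markers)) {
    own <- sum(cm[markers[[cl]], ct == cl]) / (length(markers[[cl]]) * sum(ct == cl))
    other <- sum(cm[markers[[cl]], ct != cl]) / (length(markers[[cl]]) * sum(ct != cl))
    expect_gt(own, 4 * other)
  }
  flat <- generateReference(smallConfig(seed = 5, markerFold = 1))
  fm <- SummarizedExperiment::assay(flat, "counts")
  fmk <- S4Vectors::metadata(flat)$markers
  fct <- cellType(flat)
  ratios <- sapply(names(fmk), function(cl)
    (sum(fm[fmk[[cl]], fct == cl]) / sum(fct == cl)) /
      (sum(fm[fmk[[cl]], fct != cl]) / sum(fct != cl)))
  expect_true(all(ratios < 1.5))
})

test_that("generator invariants: config validation and flag initialization", {
  expect_error(generatorConfig(doubletFraction = 1), "\\[0, 1\\)")
  expect_error(generatorConfig(nGenes = 50, markersPerType = 20),
               "marker demand")
  x <- generateReference(smallConfig(seed = 1))
  cd <- SummarizedExperiment::colData(x)
  expect_false(any(cd$is_doublet | cd$is_ambient | cd$is_mislabeled))
})

test_that("doublets are exact two-parent sums with a parent label", {
  # constant within-type profiles make the sum construction observable
  counts <- cbind(matrix(1L, 5, 10), matrix(3L, 5, 10))
  dimnames(counts) <- list(paste0("g", 1:5), sprintf("c%02d", 1:20))
  x <- AnnotatedCounts(counts, cellType = rep(c("A", "B"), each = 10),
                       tissue = rep(c("ta", "tb"), each = 10))
  d <- injectDoublets(x, 0.2, seed = 9)
  cd <- SummarizedExperiment::colData(d)
  expect_equal(sum(cd$is_doublet), scCurate:::roundHalfUp(0.2 * 20))
  dm <- as.matrix(SummarizedExperiment::assay(d, "counts"))
  for (i in which(cd$is_doublet)) {
    expect_equal(unname(dm[, i]), rep(4L, 5))  # always an A + B sum here
    expect_true(cd$cell_type[i] %in% c("A", "B"))
    expect_identical(cd$tissue[i],
                     unname(c(A = "ta", B = "tb")[cd$cell_type[i]]))
  }
  expect_identical(injectDoublets(x, 0, seed = 1), x)
  one <- AnnotatedCounts(counts, cellType = rep("A", 20),
                         tissue = rep("ta", 20))
  expect_error(injectDoublets(one, 0.2, seed = 1), "2 cell types")
})

test_that("ambient contamination pulls profiles toward the pseudo-bulk", {
  x <- generateReference(smallConfig(seed = 41, cellsPerType = 80, baseMean = 1))
  cm <- as.matrix(SummarizedExperiment::assay(x, "counts"))
  pb <- rowSums(cm) / sum(cm)
  ct <- cellType(x)
  typeMean <- vapply(sort(unique(ct)), function(cl)
    rowMeans(cm[, ct == cl]), numeric(nrow(cm)))
  # strength 0 leaves cells untouched
  expect_identical(injectAmbient(x, 0.1, strength = 0, seed = 2), x)
  # full-strength contamination resembles the pseudo-bulk more than its type
  full <- injectAmbient(x, 0.1, strength = 1, seed = 2)
  cd <- SummarizedExperiment::colData(full)
  expect_equal(sum(cd$is_ambient), scCurate:::roundHalfUp(0.1 * ncol(x)))
  fm <- as.matrix(SummarizedExperiment::assay(full, "counts"))
  for (i in which(cd$is_ambient)) {
    expect_gt(cor(fm[, i], pb), cor(fm[, i], typeMean[, ct[i]]))
    # library size preserved up to rounding (at most 1 per gene)
    expect_lte(abs(sum(fm[, i]) - sum(cm[, i])), nrow(cm))
  }
})

test_that("mislabels are wrong labels with consistent tissues", {
  x <- smallRef(6)
  orig <- cellType(x)
  ml <- injectMislabels(x, 0.1, seed = 4)
  cd <- SummarizedExperiment::colData(ml)
  expect_equal(sum(cd$is_mislabeled), scCurate:::roundHalfUp(0.1 * ncol(x)))
  expect_true(all(cd$cell_type[cd$is_mislabeled] !=
                  orig[cd$is_mislabeled]))
  expect_true(methods::validObject(ml))  # type->tissue map still consistent
  expect_identical(injectMislabels(x, 0, seed = 1), x)
})

test_that("quality control removes mislabeled cells under the assigned-label score", {
  hits <- sapply(1:3, function(sd) {
    x <- smallRef(sd, cellsPerType = 80)
    x <- injectMislabels(x, 0.05, seed = sd + 100)
    qs <- crossFitQualityScores(x, seed = 1, folds = 3)
    parts <- filterByQuality(x, qs, 0.8, score = "assigned")
    cd <- SummarizedExperiment::colData(parts$noisy)
    sum(cd$is_mislabeled) /
      sum(SummarizedExperiment::colData(x)$is_mislabeled)
  })
  expect_gte(mean(hits), 0.5)
})
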