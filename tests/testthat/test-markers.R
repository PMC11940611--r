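test_that("a gene with identical group distributions is a perfect null", {
  # same value multiset in both groups -> alternative equals null exactly
  counts <- matrix(0L, 3, 20, dimnames = list(paste0("g", 1:3),
                                              sprintf("c%02d", 1:20)))
  counts[1, ] <- rep(c(0L, 1L, 2L, 5L, 0L), 4)
  counts[2, ] <- 1L
  counts[3, 1:10] <- 4L  # a real marker for class A
  x <- makeDataset(counts, rep(c("A", "B"), each = 10))
  mt <- rankMarkers(x)
  null1 <- mt[mt$gene_id == "g1" & mt$cell_type == "A", ]
  expect_equal(null1$p_value, 1, tolerance = 1e-9)
  expect_equal(null1$ae_logfc, 0, tolerance = 1e-9)
  marker <- mt[mt$gene_id == "g3" & mt$cell_type == "A", ]
  expect_lt(marker$p_value, 0.01)
  expect_gt(marker$ae_logfc, 0)
  expect_equal(marker$rank, 1)
})

test_that("an exclusively expressed gene matches the direct likelihood oracle", {
  counts <- matrix(0L, 2, 100, dimnames = list(c("mk", "bg"),
                                               sprintf("c%03d", 1:100)))
  counts[1, 1:50] <- 5L     # expressed in every class-A cell, zero elsewhere
  counts[2, ] <- rep(c(1L, 0L), 50)
  x <- makeDataset(counts, rep(c("A", "B"), each = 50))
  mt <- rankMarkers(x)
  row <- mt[mt$gene_id == "mk" & mt$cell_type == "A", ]
  expect_lt(row$p_value, 1e-10)
  expect_gt(row$ae_logfc, 0)
  # oracle: evaluate the mixture log-likelihoods directly on the raw values
  v <- log1p(counts[1, ])
  lr <- 2 * (bimodLogLik(v[1:50]) + bimodLogLik(v[51:100]) - bimodLogLik(v))
  expect_equal(row$p_value, pchisq(lr, df = 3, lower.tail = FALSE),
               tolerance = 1e-9)
  # ae_logfc against its definition
  fcOracle <- log1p(mean(expm1(v[1:50]))) - log1p(mean(expm1(v[51:100])))
  expect_equal(row$ae_logfc, unname(fcOracle), tolerance = 1e-12)
})

test_that("p-values stay in [0, 1] on random data and the null is calibrated", {
  x <- smallRef(13, nGenes = 400, nTissues = 5)
  mt <- rankMarkers(x)
  expect_true(all(mt$p_value >= 0 & mt$p_value <= 1))
  # label permutation kills the signal: close to nominal at alpha = 0.05
  set.seed(11)
  perm <- sample(cellType(x))
  mtp <- rankMarkers(x, labels = perm)
  expect_gte(nrow(mtp), 2000)
  frac <- mean(mtp$p_value < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("marker selection sizes follow topN and eligibility", {
  x <- smallRef(14, nGenes = 300, markersPerType = 35)
  mt <- rankMarkers(x)
  for (n in c(1, 3, 5, 10, 30)) {
    sel <- selectMarkers(mt, n)
    expect_true(all(table(sel$cell_type) == n))
    expect_true(all(sel$ae_logfc > 0))
  }
  # topN beyond the gene count returns every eligible gene
  all <- selectMarkers(mt, 1e6)
  expect_equal(nrow(all), sum(mt$ae_logfc > 0))
  # stable under row shuffling of the table
  set.seed(3)
  shuffled <- selectMarkers(mt[sample(nrow(mt)), ], 5)
  expect_equal(shuffled[order(shuffled$cell_type, shuffled$rank), ],
               selectMarkers(mt, 5)[order(selectMarkers(mt, 5)$cell_type,
                                          selectMarkers(mt, 5)$rank), ],
               ignore_attr = TRUE)
})

test_that("majority vote is exact for exclusive markers and breaks ties lexicographically", {
  counts <- matrix(0L, 2, 4, dimnames = list(c("mA", "mB"),
                                             c("c1", "c2", "c3", "c4")))
  counts[1, 1:2] <- 3L  # cells 1-2 express only A's marker
  counts[2, 3] <- 2L    # cell 3 expresses only B's marker
  counts[, 4] <- 1L     # cell 4 expresses both -> tie -> "A"
  x <- makeDataset(counts, c("A", "A", "B", "B"))
  markers <- data.frame(gene_id = c("mA", "mB"), cell_type = c("A", "B"),
                        p_value = 0, ae_logfc = 1, rank = 1)
  res <- mgmvClassify(x, markers)
  expect_identical(res$predicted_class[1:3], c("A", "A", "B"))
  expect_identical(res$predicted_class[4], "A")
  expect_true(res$tie[4])
  expect_false(any(res$tie[1:3]))
  # a cell expressing no marker at all is unassigned
  counts2 <- counts; counts2[, 4] <- 0L
  res2 <- mgmvClassify(makeDataset(counts2, c("A", "A", "B", "B")), markers)
  expect_identical(res2$predicted_class[4], "unassigned")
  # vote normalization keeps classes with fewer markers competitive
  expect_equal(mean(res$predicted_class[1:3] ==
                    c("A", "A", "B")), 1)
})

test_that("a marker shared between classes degrades MGMV accuracy", {
  accs <- sapply(1:6, function(sd) {
    run <- function(shared) {
      z <- smallRef(sd, markersPerType = 3, sharedMarkers = shared)
      sel <- selectMarkers(rankMarkers(z), 3)
      mean(mgmvClassify(z, sel)$predicted_class == cellType(z))
    }
    c(excl = run(FALSE), shared = run(TRUE))
  })
  expect_lt(mean(accs["shared", ]), mean(accs["excl", ]))
})

test_that("marker analysis rejects undersized classes", {
  counts <- matrix(1L, 3, 5, dimnames = list(paste0("g", 1:3),
                                             paste0("c", 1:5)))
  x <- makeDataset(counts, c("A", "A", "A", "B", "B"))
  expect_error(rankMarkers(x), "fewer than 3 cells")
})
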