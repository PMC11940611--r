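test_that("PCA detects rank deficiency and maps duplicate cells identically", {
  # only two distinct cell profiles -> the log matrix has rank <= 2
  set.seed(4)
  p1 <- rpois(40, 3); p2 <- rpois(40, 1)
  m <- cbind(sapply(1:6, function(i) p1), sapply(1:6, function(i) p2))
  dimnames(m) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:12))
  x <- computePCA(logTransform(AnnotatedCounts(m)), nComponents = 5)
  ev <- S4Vectors::metadata(x)$pca_explained_variance
  expect_true(sum(ev[3:5]) <= 1e-8 * sum(ev))
  emb <- SingleCellExperiment::reducedDim(x, "PCA")
  expect_equal(emb[1, ], emb[2, ], tolerance = 1e-9)
  expect_equal(emb[7, ], emb[12, ], tolerance = 1e-9)
})

test_that("full-rank PCA agrees with the eigendecomposition oracle", {
  set.seed(7)
  m <- matrix(rpois(200 * 50, 2), 50, 200,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%03d", 1:200)))
  x <- computePCA(logTransform(AnnotatedCounts(m)), nComponents = 50)
  lp <- t(log1p(m))
  centered <- scale(lp, center = TRUE, scale = FALSE)
  # independent oracle: eigenvalues of the covariance matrix
  ev <- S4Vectors::metadata(x)$pca_explained_variance
  eig <- eigen(stats::cov(centered), symmetric = TRUE, only.values = TRUE)
  expect_equal(ev, eig$values[seq_along(ev)], tolerance = 1e-8)
  expect_true(all(diff(ev) <= 1e-9))  # non-increasing order
  # full set of components is an isometry => lossless reconstruction
  emb <- SingleCellExperiment::reducedDim(x, "PCA")
  expect_equal(unname(rowSums(emb^2)), unname(rowSums(centered^2)),
               tolerance = 1e-8)
})

test_that("PCA rejects infeasible component counts", {
  x <- smallRef(1)
  expect_error(computePCA(x, nComponents = 1000), "exceeds")
})

test_that("kNN graph follows Euclidean geometry", {
  # three collinear points: the middle one is nearest neighbor of both ends
  emb <- cbind(c(0, 1, 2.5), 0)
  rownames(emb) <- c("a", "b", "c")
  g <- buildKnnGraph(emb, k = 1)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "b", "c"))
  expect_false(igraph::are_adjacent(g, "a", "c"))
  # two far-separated blobs: no cross-blob edges at k = 5
  set.seed(1)
  blob <- rbind(matrix(rnorm(100), 50, 2),
                matrix(rnorm(100, mean = 100), 50, 2))
  rownames(blob) <- sprintf("p%03d", 1:100)
  g2 <- buildKnnGraph(blob, k = 5)
  el <- igraph::as_edgelist(g2, names = FALSE)
  sameBlob <- (el[, 1] <= 50) == (el[, 2] <= 50)
  # oracle: exhaustive pairwise distances put every within-blob pair closer
  # than any cross-blob pair
  d <- as.matrix(dist(blob))
  expect_lt(max(d[1:50, 1:50]), min(d[1:50, 51:100]))
  expect_true(all(sameBlob))
  # k = n - 1 gives the complete graph
  g3 <- buildKnnGraph(blob[1:8, ], k = 7)
  expect_equal(igraph::ecount(g3), choose(8, 2))
  expect_error(buildKnnGraph(blob, k = 0), "positive")
  expect_error(buildKnnGraph(blob[1:4, ], k = 4), "smaller")
})

test_that("Louvain separates disconnected cliques and reports true modularity", {
  g <- igraph::make_full_graph(5) + igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("v", 1:10)
  cl <- louvainCluster(g, seed = 3)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(unname(cl$labels[1:5]), rep(cl$labels[[1]], 5))
  expect_true(min(cl$labels) == 0)  # contiguous ids from 0
  # independent modularity computation from the edge list:
  # Q = sum_c [ e_c/m - (d_c/(2m))^2 ]
  el <- igraph::as_edgelist(g, names = FALSE)
  memb <- cl$labels[igraph::V(g)$name]
  m <- nrow(el)
  q <- 0
  for (c in unique(memb)) {
    inC <- sum(memb[el[, 1]] == c & memb[el[, 2]] == c)
    dC <- sum(igraph::degree(g)[memb == c])
    q <- q + inC / m - (dC / (2 * m))^2
  }
  expect_equal(cl$modularity, q, tolerance = 1e-9)
  expect_error(louvainCluster(igraph::make_empty_graph(0)), "empty")
})

test_that("phase-1 pipeline recovers generator labels and is order-invariant", {
  x <- smallRef(1)
  xc <- clusterReference(x, nComponents = 10, k = 30, seed = 1)
  labels <- SummarizedExperiment::colData(xc)$cluster
  expect_equal(ariScore(cellType(xc), labels), 1.0)
  expect_equal(S4Vectors::metadata(xc)$modularity,
               louvainCluster(buildKnnGraph(computePCA(x, 10), k = 30),
                              seed = 1)$modularity)
  # permuting the cells changes nothing up to label renaming
  set.seed(9)
  perm <- sample(ncol(x))
  xp <- clusterReference(x[, perm], nComponents = 10, k = 30, seed = 1)
  expect_equal(ariScore(SummarizedExperiment::colData(xp)$cluster,
                        labels[perm]), 1.0)
})

test_that("resolution tuning scores the grid by ARI and flags the best row", {
  x <- smallRef(2)
  tab <- tuneResolution(x, cellType(x), resolutions = c(0.5, 1),
                        nComponents = 10, k = 30, seed = 1)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$best), 1)
  expect_true(all(tab$ari <= 1 & tab$ari >= -1))
  expect_equal(tab$ari[tab$best], max(tab$ari))
})
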