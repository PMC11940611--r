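#' Principal component embedding of log-transformed counts
#'
#' Projects cells onto the top principal components of the mean-centered
#' natural-log expression matrix (no per-gene scaling). The embedding is
#' stored as the `"PCA"` entry of `reducedDims`, with the per-component
#' explained variance in `metadata(x)$pca_explained_variance`.
#'
#' @param x an [AnnotatedCounts-class] object.
#' @param nComponents number of components (default 30).
#' @param seed accepted for interface symmetry; the deterministic full
#'   decomposition does not consume randomness.
#' @return `x` with the PCA embedding attached.
#' @export
computePCA <- function(x, nComponents = 30, seed = 1) {
  if (ncol(x) < 2) stop("at least 2 cells are required")
  if (nComponents > min(dim(x)))
    stop("nComponents exceeds min(cells, genes)")
  mat <- t(as.matrix(.logProfile(x)))  # cells x genes
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE, rank. = nComponents)
  coords <- p$x
  if (ncol(coords) < nComponents)  # prcomp may return fewer on tiny input
    coords <- cbind(coords, matrix(0, nrow(coords), nComponents - ncol(coords)))
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  SingleCellExperiment::reducedDim(x, "PCA") <- coords
  ev <- p$sdev^2
  S4Vectors::metadata(x)$pca_explained_variance <-
    ev[seq_len(min(nComponents, length(ev)))]
  x
}

#' Euclidean k-nearest-neighbor graph over an embedding
#'
#' Connects each cell to its `k` nearest neighbors by Euclidean distance in
#' the PCA embedding; the directed k-NN relation is symmetrized by union
#' into an unweighted, undirected simple graph.
#'
#' @param x an [AnnotatedCounts-class] with a `"PCA"` reducedDim, or a
#'   numeric cells x dims matrix.
#' @param k neighbors per cell (default 20); must satisfy `0 < k < cells`.
#' @return an [igraph::graph] with vertices named by cell id.
#' @export
buildKnnGraph <- function(x, k = 20) {
  emb <- if (is.matrix(x)) x else SingleCellExperiment::reducedDim(x, "PCA")
  n <- nrow(emb)
  if (k <= 0) stop("k must be positive")
  if (n <= k) stop("k must be smaller than the number of cells")
  # exact neighbors from the full pairwise distance matrix
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  nb <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- if (is.null(rownames(emb)))
    as.character(seq_len(n)) else rownames(emb)
  g
}

#' Louvain community detection on a cell similarity graph
#'
#' Runs Louvain modularity optimization at the given resolution. Node-order
#' tie-breaking is fixed by a seed-derived shuffle, so results are
#' reproducible. The reported modularity is the (resolution-1) Newman
#' modularity of the returned partition, recomputed from the edge list.
#'
#' @param g an undirected [igraph::graph].
#' @param resolution Louvain resolution (default 1.0).
#' @param seed integer seed fixing tie-breaks.
#' @return list with `labels` (named integer vector, community ids
#'   contiguous from 0) and `modularity`.
#' @export
louvainCluster <- function(g, resolution = 1.0, seed = 1) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  names(labels) <- igraph::V(g)$name
  list(labels = labels,
       modularity = igraph::modularity(g, labels + 1L))
}

#' Phase 1: cluster a reference by PCA, k-NN graph and Louvain
#'
#' Convenience pipeline: [computePCA()] then [buildKnnGraph()] then
#' [louvainCluster()]. Cluster ids are written to `colData(x)$cluster` and
#' the partition modularity to `metadata(x)$modularity`.
#'
#' @inheritParams computePCA
#' @inheritParams buildKnnGraph
#' @inheritParams louvainCluster
#' @return `x` with a `cluster` column in `colData`.
#' @export
clusterReference <- function(x, nComponents = 30, k = 20, resolution = 1.0,
                             seed = 1) {
  x <- computePCA(x, nComponents = nComponents, seed = seed)
  g <- buildKnnGraph(x, k = k)
  cl <- louvainCluster(g, resolution = resolution, seed = seed)
  SummarizedExperiment::colData(x)$cluster <- unname(cl$labels)
  S4Vectors::metadata(x)$modularity <- cl$modularity
  x
}

#' Tune the Louvain resolution against known labels
#'
#' Grid-searches the resolution, scoring each candidate partition by its
#' adjusted Rand index against reference labels, and returns the full table
#' with the best row marked.
#'
#' @param x an [AnnotatedCounts-class] object.
#' @param trueLabels per-cell ground-truth labels.
#' @param resolutions numeric vector of candidate resolutions.
#' @inheritParams clusterReference
#' @return data.frame with columns resolution, nClusters, ari, best.
#' @export
tuneResolution <- function(x, trueLabels,
                           resolutions = c(0.25, 0.5, 1, 2, 4),
                           nComponents = 30, k = 20, seed = 1) {
  stopifnot(length(trueLabels) == ncol(x))
  x <- computePCA(x, nComponents = nComponents, seed = seed)
  g <- buildKnnGraph(x, k = k)
  rows <- lapply(resolutions, function(r) {
    cl <- louvainCluster(g, resolution = r, seed = seed)
    data.frame(resolution = r, nClusters = length(unique(cl$labels)),
               ari = ariScore(trueLabels, cl$labels))
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.max(out$ari)
  out
}
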