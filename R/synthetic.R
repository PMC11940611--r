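#' Configuration for the synthetic multi-tissue count generator
#'
#' Defines a negative-binomial count model over `nTissues * cellTypesPerTissue`
#' cell types: every gene has baseline mean `baseMean`, each cell type's
#' `markersPerType` marker genes have mean `baseMean * markerFold`, per-cell
#' library-size factors are log-normal with coefficient of variation
#' `librarySizeCV`, and counts are NB with dispersion (size) `dispersion`.
#' Noise injections (doublets, ambient contamination, mislabels) are applied
#' separately by the `inject*` functions; their default fractions here are 0.
#'
#' @param nTissues number of tissues (default 5).
#' @param cellTypesPerTissue cell types per tissue (default 2).
#' @param cellsPerType cells per cell type (default 300).
#' @param nGenes genes (default 2000).
#' @param markersPerType marker genes per cell type (default 20).
#' @param markerFold mean multiplier for markers (default 8).
#' @param baseMean baseline NB mean per gene (default 0.2).
#' @param dispersion NB size parameter (default 2).
#' @param librarySizeCV CV of log-normal library-size factors (default 0.3).
#' @param doubletFraction,ambientFraction,mislabelFraction noise fractions
#'   in \[0, 1) (defaults 0).
#' @param ambientStrength mixing weight of the ambient profile in \[0, 1\]
#'   (default 0.8): flagged cells are soup-dominated, emulating droplets
#'   noisy enough to fail reference quality control.
#' @param sharedMarkers if TRUE, each cell type shares its first marker
#'   gene with the next cell type (cyclically), emulating markers common to
#'   functionally different types across tissues.
#' @param seed integer seed.
#' @return a validated `GeneratorConfig` (list).
#' @export
generatorConfig <- function(nTissues = 5, cellTypesPerTissue = 2,
                            cellsPerType = 300, nGenes = 2000,
                            markersPerType = 20, markerFold = 8,
                            baseMean = 0.2, dispersion = 2,
                            librarySizeCV = 0.3, doubletFraction = 0,
                            ambientFraction = 0, ambientStrength = 0.8,
                            mislabelFraction = 0, sharedMarkers = FALSE,
                            seed = 1) {
  cfg <- as.list(environment())
  for (f in c("doubletFraction", "ambientFraction", "mislabelFraction"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stop(f, " must lie in [0, 1)")
  if (ambientStrength < 0 || ambientStrength > 1)
    stop("ambientStrength must lie in [0, 1]")
  nTypes <- nTissues * cellTypesPerTissue
  if (nTypes * markersPerType > nGenes)
    stop("marker demand exceeds the number of genes")
  structure(cfg, class = "GeneratorConfig")
}

#' @export
print.GeneratorConfig <- function(x, ...) {
  cat("GeneratorConfig:", x$nTissues, "tissues x", x$cellTypesPerTissue,
      "types x", x$cellsPerType, "cells;", x$nGenes, "genes\n")
  invisible(x)
}

#' Generate a synthetic labeled reference
#'
#' Draws counts from the model in [generatorConfig()]. Cell types are named
#' `tissue<i>_type<j>`, tissues `tissue<i>`; truth flags `is_doublet`,
#' `is_ambient`, `is_mislabeled` start all-FALSE in `colData`. The marker
#' assignment is recorded in `metadata(x)$markers` and the config in
#' `metadata(x)$config`. Fully reproducible from the config seed.
#'
#' @param cfg a [generatorConfig()].
#' @return a labeled [AnnotatedCounts-class].
#' @export
generateReference <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(cfg$seed)
  nTypes <- cfg$nTissues * cfg$cellTypesPerTissue
  tissues <- rep(sprintf("tissue%d", seq_len(cfg$nTissues)),
                 each = cfg$cellTypesPerTissue)
  types <- sprintf("%s_type%d", tissues,
                   rep(seq_len(cfg$cellTypesPerTissue), cfg$nTissues))
  geneIdsAll <- sprintf("gene%04d", seq_len(cfg$nGenes))
  markers <- lapply(seq_len(nTypes), function(ti)
    geneIdsAll[((ti - 1) * cfg$markersPerType + 1):(ti * cfg$markersPerType)])
  names(markers) <- types
  if (cfg$sharedMarkers)  # first marker borrowed from the next type
    for (ti in seq_len(nTypes))
      markers[[ti]][1] <- markers[[ti %% nTypes + 1]][2]
  sdlog <- sqrt(log(1 + cfg$librarySizeCV^2))
  blocks <- vector("list", nTypes)
  for (ti in seq_len(nTypes)) {
    mu <- rep(cfg$baseMean, cfg$nGenes)
    mu[match(markers[[ti]], geneIdsAll)] <- cfg$baseMean * cfg$markerFold
    f <- exp(stats::rnorm(cfg$cellsPerType, -sdlog^2 / 2, sdlog))
    m <- matrix(stats::rnbinom(cfg$nGenes * cfg$cellsPerType,
                               mu = mu %o% f, size = cfg$dispersion),
                cfg$nGenes, cfg$cellsPerType)
    blocks[[ti]] <- Matrix::Matrix(m, sparse = TRUE)
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- geneIdsAll
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  ct <- rep(types, each = cfg$cellsPerType)
  ti <- rep(tissues, each = cfg$cellsPerType)
  x <- AnnotatedCounts(counts, cellType = ct, tissue = ti)
  cd <- SummarizedExperiment::colData(x)
  cd$is_doublet <- cd$is_ambient <- cd$is_mislabeled <- FALSE
  SummarizedExperiment::colData(x) <- cd
  S4Vectors::metadata(x)$markers <- markers
  S4Vectors::metadata(x)$config <- cfg
  x
}

#' Inject artificial doublets
#'
#' Replaces `roundHalfUp(fraction * n)` randomly chosen cells with the
#' elementwise sum of two randomly chosen cells of different cell types
#' (the physical two-cells-in-one-droplet model, which places the profile
#' between the two parent clusters after log transform). The label becomes
#' one parent's label at random; `is_doublet` is set.
#'
#' @param x a labeled [AnnotatedCounts-class].
#' @param fraction fraction of cells to replace, in \[0, 1).
#' @param seed integer seed.
#' @return `x` with doublets injected and flagged.
#' @export
injectDoublets <- function(x, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(x)
  ct <- cellType(x)
  if (length(unique(ct)) < 2) stop("at least 2 cell types are required")
  set.seed(seed)
  n <- ncol(x)
  m <- roundHalfUp(fraction * n)
  targets <- sample.int(n, m)
  counts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
  orig <- counts  # parents are drawn from the uncontaminated matrix
  map <- typeTissueMap(x)
  cd <- SummarizedExperiment::colData(x)
  if (is.null(cd$is_doublet)) cd$is_doublet <- rep(FALSE, n)
  for (i in targets) {
    p1 <- sample.int(n, 1)
    repeat {
      p2 <- sample.int(n, 1)
      if (ct[p2] != ct[p1]) break
    }
    counts[, i] <- orig[, p1] + orig[, p2]
    lab <- ct[sample(c(p1, p2), 1)]
    cd$cell_type[i] <- lab
    cd$tissue[i] <- unname(map[lab])
  }
  cd$is_doublet[targets] <- TRUE
  SummarizedExperiment::assay(x, "counts") <- Matrix::Matrix(counts,
                                                             sparse = TRUE)
  SummarizedExperiment::colData(x) <- cd
  if ("log1p" %in% SummarizedExperiment::assayNames(x)) x <- logTransform(x)
  x
}

#' Inject ambient mRNA contamination
#'
#' For `roundHalfUp(fraction * n)` randomly chosen cells, replaces counts by
#' `roundHalfUp((1 - strength) * own + strength * ambient * libSize)`, where
#' `ambient` is the dataset's normalized pseudo-bulk profile, so the cell is
#' pulled toward the sample average while approximately preserving its
#' library size. `is_ambient` is set.
#'
#' @param x an [AnnotatedCounts-class].
#' @param fraction fraction of cells to contaminate, in \[0, 1).
#' @param strength mixing weight in \[0, 1\].
#' @param seed integer seed.
#' @return `x` with contaminated cells flagged.
#' @export
injectAmbient <- function(x, fraction, strength = 0.5, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1, strength >= 0, strength <= 1)
  if (fraction == 0 || strength == 0) return(x)
  set.seed(seed)
  n <- ncol(x)
  m <- roundHalfUp(fraction * n)
  targets <- sample.int(n, m)
  counts <- as.matrix(SummarizedExperiment::assay(x, "counts"))
  ambient <- rowSums(counts) / sum(counts)
  lib <- colSums(counts)
  for (i in targets)
    counts[, i] <- roundHalfUp((1 - strength) * counts[, i] +
                               strength * ambient * lib[i])
  SummarizedExperiment::assay(x, "counts") <- Matrix::Matrix(counts,
                                                             sparse = TRUE)
  cd <- SummarizedExperiment::colData(x)
  if (is.null(cd$is_ambient)) cd$is_ambient <- rep(FALSE, n)
  cd$is_ambient[targets] <- TRUE
  SummarizedExperiment::colData(x) <- cd
  if ("log1p" %in% SummarizedExperiment::assayNames(x)) x <- logTransform(x)
  x
}

#' Inject incorrect cell type labels
#'
#' Gives `roundHalfUp(fraction * n)` randomly chosen cells a uniformly
#' random WRONG cell-type label (tissue follows the new label, preserving
#' the type-to-tissue invariant); `is_mislabeled` is set.
#'
#' @inheritParams injectDoublets
#' @export
injectMislabels <- function(x, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(x)
  ct <- cellType(x)
  classes <- unique(ct)
  if (length(classes) < 2) stop("at least 2 cell types are required")
  set.seed(seed)
  n <- ncol(x)
  targets <- sample.int(n, roundHalfUp(fraction * n))
  map <- typeTissueMap(x)
  cd <- SummarizedExperiment::colData(x)
  if (is.null(cd$is_mislabeled)) cd$is_mislabeled <- rep(FALSE, n)
  for (i in targets) {
    wrong <- sample(setdiff(classes, ct[i]), 1)
    cd$cell_type[i] <- wrong
    cd$tissue[i] <- unname(map[wrong])
  }
  cd$is_mislabeled[targets] <- TRUE
  SummarizedExperiment::colData(x) <- cd
  x
}
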