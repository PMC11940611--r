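# Small generator configurations used across the suite. Three well-separated
# one-type tissues keep SVM fits and clustering fast; tests that need the
# full-scale defaults build them explicitly.
smallConfig <- function(seed = 42, nTissues = 3, cellTypesPerTissue = 1,
                        cellsPerType = 60, nGenes = 300,
                        markersPerType = 10, ...) {
  generatorConfig(nTissues = nTissues,
                  cellTypesPerTissue = cellTypesPerTissue,
                  cellsPerType = cellsPerType, nGenes = nGenes,
                  markersPerType = markersPerType, seed = seed, ...)
}

smallRef <- function(seed = 42, ...) {
  logTransform(generateReference(smallConfig(seed = seed, ...)))
}

# labeled dataset built from an explicit count matrix
makeDataset <- function(counts, cellType, tissue = cellType) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%04d", seq_len(ncol(counts)))
  logTransform(AnnotatedCounts(counts, cellType = cellType, tissue = tissue))
}

# Brute-force adjusted Rand index by explicit enumeration of all cell pairs
# (the independent oracle for the contingency-table implementation).
bruteAri <- function(a, b) {
  n <- length(a)
  sameA <- sameB <- sameBoth <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      sameA <- sameA + sa
      sameB <- sameB + sb
      sameBoth <- sameBoth + (sa && sb)
    }
  }
  total <- n * (n - 1) / 2
  expected <- sameA * sameB / total
  maxIdx <- (sameA + sameB) / 2
  if (maxIdx == expected) return(1)
  (sameBoth - expected) / (maxIdx - expected)
}

# Mann-Whitney AUC: probability that a score from `high` exceeds one from `low`
rankAuc <- function(high, low) {
  r <- rank(c(high, low))
  (sum(r[seq_along(high)]) - length(high) * (length(high) + 1) / 2) /
    (length(high) * length(low))
}

# direct log-likelihood of the zero/positive mixture on a raw value vector
# (independent oracle for the sufficient-statistics implementation)
bimodLogLik <- function(v, varFloor = 0.05) {
  n0 <- sum(v == 0)
  pos <- v[v > 0]
  n <- length(v)
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(n0 / n)
  if (length(pos) > 0) {
    ll <- ll + length(pos) * log(1 - n0 / n)
    mu <- mean(pos)
    ss <- sum((pos - mu)^2)
    sig2 <- max(ss / length(pos), varFloor)
    ll <- ll - length(pos) / 2 * log(2 * pi * sig2) - ss / (2 * sig2)
  }
  ll
}
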