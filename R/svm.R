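# Platt's probability calibration: fit (A, B) of P(y=1|s) = 1/(1+exp(A*s+B))
# by regularized maximum likelihood with the smoothed targets of Platt
# (1999), using the robust Newton iteration of Lin, Huang & Weng (2007).
.plattCalibrate <- function(scores, positive, maxIter = 100,
                            minStep = 1e-10, sigma = 1e-12) {
  n1 <- sum(positive); n0 <- sum(!positive)
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n0 + 2)
  t <- ifelse(positive, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  fApB <- scores * A + B
  fval <- sum(ifelse(fApB >= 0,
                     t * fApB + log1p(exp(-fApB)),
                     (t - 1) * fApB + log1p(exp(fApB))))
  for (it in seq_len(maxIter)) {
    fApB <- scores * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(scores * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(scores^2 * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(scores * d2)
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= minStep) {
      newA <- A + step * dA; newB <- B + step * dB
      fApB <- scores * newA + newB
      newf <- sum(ifelse(fApB >= 0,
                         t * fApB + log1p(exp(-fApB)),
                         (t - 1) * fApB + log1p(exp(fApB))))
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < minStep) break
  }
  # probability must increase with the decision score (A strictly negative)
  if (A >= 0) {
    A <- -1e-6
    B <- -A * stats::median(scores)
  }
  c(A = A, B = B)
}

# One-vs-rest linear SVM on the log1p profile (genes x cells sparse).
# Returns weights (genes x classes) and biases fitted to the hinge-loss
# dual by coordinate descent; the bias enters through an implicit unit
# feature. maxIter caps the epochs (deterministic given seed); solutions
# are at worst slightly inexact for hard, noisy classes, which predictions
# are insensitive to.
.fitOVRraw <- function(lp, labels, C, tol, seed, maxIter = 400) {
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("at least 2 classes are required")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("class '", names(sizes)[which(sizes < 2)[1]],
         "' has fewer than 2 cells; cannot calibrate")
  lp <- methods::as(lp, "CsparseMatrix")
  d <- nrow(lp)
  W <- matrix(0, d, length(classes),
              dimnames = list(rownames(lp), classes))
  biases <- setNames(numeric(length(classes)), classes)
  seeds <- .subSeeds(seed, length(classes))
  biasScale <- 10  # liblinear-style -B: keeps the intercept ridge negligible
  for (ci in seq_along(classes)) {
    y <- ifelse(labels == classes[ci], 1, -1)
    set.seed(seeds[ci])
    fit <- .dcd_svm(lp, y, C, tol, maxIter, biasScale)
    W[, ci] <- fit$w[seq_len(d)]
    biases[ci] <- fit$w[d + 1] * biasScale
  }
  list(classes = classes, W = W, biases = unname(biases))
}

# raw fit plus per-class Platt calibration on in-sample decision scores
.fitOVR <- function(lp, labels, C, tol, seed, maxIter = 400) {
  raw <- .fitOVRraw(lp, labels, C, tol, seed, maxIter)
  s <- as.matrix(Matrix::crossprod(lp, raw$W))
  s <- sweep(s, 2, raw$biases, "+")
  calibA <- calibB <- numeric(length(raw$classes))
  for (ci in seq_along(raw$classes)) {
    ab <- .plattCalibrate(s[, ci], labels == raw$classes[ci])
    calibA[ci] <- ab["A"]; calibB[ci] <- ab["B"]
  }
  .newCellTypeModel(classes = raw$classes, geneIds = rownames(lp),
                    weights = raw$W, biases = raw$biases,
                    calibA = calibA, calibB = calibB, C = C, tol = tol)
}

# new("CellTypeModel", C = ...) would partially match new()'s Class formal;
# route slot assignment through initialize() instead
.newCellTypeModel <- function(...)
  methods::initialize(methods::new("CellTypeModel"), ...)

#' Fit the reclassification SVM on a labeled reference
#'
#' Phase 2 learner: a one-vs-rest soft-margin linear SVM (L2 regularizer
#' \eqn{\tfrac12 \omega^\top\omega}, hinge loss, cost `C`) fitted on the
#' natural-log expression \eqn{\phi(x) = \ln(1+x)}, followed by a per-class
#' logistic (Platt) calibration of the decision scores, so that the quality
#' probability \eqn{P_c = 1/(1+\exp(A_c s_c + B_c))} increases with the
#' class margin (\eqn{A_c < 0}).
#'
#' @param x a labeled [AnnotatedCounts-class] object.
#' @param labels per-cell class labels; defaults to `cellType(x)`.
#' @param C soft-margin cost (default 1.0).
#' @param tol optimizer stopping tolerance (default 1e-4).
#' @param seed integer seed fixing the coordinate-descent sweep order.
#' @return a [CellTypeModel-class].
#' @export
fitReclassifier <- function(x, labels = cellType(x), C = 1.0, tol = 1e-4,
                            seed = 1) {
  if (is.null(labels)) stop("labels are required")
  stopifnot(length(labels) == ncol(x))
  .fitOVR(.logProfile(x), as.character(labels), C, tol, seed)
}

#' Train the final classifier on a quality-controlled reference
#'
#' Phase 3 shares the phase-2 learner: identical fitting contract to
#' [fitReclassifier()]. A warning is emitted when two classes have
#' indistinguishable mean profiles (correlation > 0.999), a degenerate
#' reference that still returns a model.
#'
#' @inheritParams fitReclassifier
#' @return a [CellTypeModel-class].
#' @export
trainClassifier <- function(x, labels = cellType(x), C = 1.0, tol = 1e-4,
                            seed = 1) {
  if (is.null(labels)) stop("labels are required")
  stopifnot(length(labels) == ncol(x))
  lp <- .logProfile(x)
  cls <- sort(unique(as.character(labels)))
  if (length(cls) >= 2) {
    means <- vapply(cls, function(cl)
      Matrix::rowMeans(lp[, labels == cl, drop = FALSE]), numeric(nrow(lp)))
    cc <- suppressWarnings(stats::cor(means))
    cc[!is.finite(cc)] <- 1
    diag(cc) <- 0
    if (any(cc > 0.999)) {
      pair <- which(cc > 0.999, arr.ind = TRUE)[1, ]
      warning("classes '", cls[pair[1]], "' and '", cls[pair[2]],
              "' have near-identical mean profiles")
    }
  }
  .fitOVR(lp, as.character(labels), C, tol, seed)
}

#' @rdname accessors
#' @export
setMethod("modelClasses", "CellTypeModel", function(x) x@classes)

setMethod("show", "CellTypeModel", function(object) {
  cat("CellTypeModel:", length(object@classes), "classes,",
      length(object@geneIds), "genes\n")
  cat("  C =", object@C, " tol =", object@tol, "\n")
  cat("  classes:", paste(utils::head(object@classes, 6), collapse = ", "),
      if (length(object@classes) > 6) "..." else "", "\n")
})

# decision scores s = W'phi + b and calibrated probabilities for a log1p
# matrix, matching model genes to data genes by exact id on the intersection
# (genes absent from either side drop out of the score)
.modelScores <- function(model, lp) {
  common <- intersect(model@geneIds, rownames(lp))
  if (length(common) == 0) stop("no genes shared between model and data")
  W <- model@weights[match(common, model@geneIds), , drop = FALSE]
  s <- as.matrix(Matrix::crossprod(lp[common, , drop = FALSE], W))
  s <- sweep(s, 2, model@biases, "+")
  colnames(s) <- model@classes
  p <- 1 / (1 + exp(sweep(sweep(s, 2, model@calibA, "*"), 2,
                          model@calibB, "+")))
  list(scores = s, prob = p)
}

#' Serialize a CellTypeModel to JSON
#'
#' Weights are stored as sparse (gene index, class index, value) triplets;
#' the file carries classes, biases, calibration pairs, gene ids,
#' hyperparameters and a format-version field. [readModel()] restores an
#' identical model.
#'
#' @param model a [CellTypeModel-class].
#' @param path output file.
#' @export
writeModel <- function(model, path) {
  nz <- which(model@weights != 0, arr.ind = TRUE)
  obj <- list(
    format_version = 1L,
    classes = model@classes,
    gene_ids = model@geneIds,
    biases = model@biases,
    calib_A = model@calibA,
    calib_B = model@calibB,
    C = model@C, tol = model@tol,
    n_genes = nrow(model@weights),
    weights = list(gene = unname(nz[, 1]), class = unname(nz[, 2]),
                   value = unname(model@weights[nz])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported model format version")
  W <- matrix(0, obj$n_genes, length(obj$classes),
              dimnames = list(obj$gene_ids, obj$classes))
  W[cbind(obj$weights$gene, obj$weights$class)] <- obj$weights$value
  .newCellTypeModel(classes = obj$classes, geneIds = obj$gene_ids,
                    weights = W, biases = obj$biases, calibA = obj$calib_A,
                    calibB = obj$calib_B, C = obj$C, tol = obj$tol)
}
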