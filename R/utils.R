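#' @keywords internal
"_PACKAGE"

#' @useDynLib scCurate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is new validObject as
#' @importFrom stats prcomp pchisq median setNames sd var
NULL

# deterministic half-up rounding (round() in R is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

# AUC for "scores separate group A (high) from group B (low)" via the
# rank-sum statistic; used to quantify how well maxProb ranks pure cells
# above injected-noise cells
.rankAuc <- function(high, low) {
  r <- rank(c(high, low))
  n1 <- length(high); n2 <- length(low)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# derive a stream of sub-seeds below 2^31 from one user seed
.subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
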