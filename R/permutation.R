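#' Lower empirical percentile
#'
#' The pinned percentile definition used by the permutation decision rule:
#' the order statistic at 1-based index `ceiling(q / 100 * n)` of the
#' sorted values -- a lower tail bound, without interpolation. Requires
#' enough values that the index is at least 1 (e.g. >= 100 values for
#' q = 1).
#'
#' @param values numeric vector.
#' @param q percentile in (0, 100).
#' @return The q-th lower empirical percentile.
#' @export
#' @examples
#' lowerPercentile(1:100, 1)  # first order statistic: 1
lowerPercentile <- function(values, q) {
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)")
  n <- length(values)
  if (n * q / 100 < 1)
    stop(sprintf("need at least %d values for the %g-th percentile; got %d",
                 ceiling(100 / q), q, n))
  sort(values)[ceiling(q / 100 * n)]
}

## Coerce scan-level fingerprints (list of Fingerprint objects or a
## scans x 8 matrix) to a matrix in canonical column order.
fingerprintMatrix <- function(scans) {
  if (is.matrix(scans)) {
    if (ncol(scans) != 8L)
      stop("scan-level fingerprint matrix must have 8 columns")
    if (!is.null(colnames(scans))) {
      if (!setequal(colnames(scans), canonicalTargets()))
        stop("fingerprint columns must be the canonical targets")
      scans <- scans[, canonicalTargets(), drop = FALSE]
    } else {
      colnames(scans) <- canonicalTargets()
    }
    return(scans)
  }
  m <- do.call(rbind, lapply(scans, function(f) {
    if (is(f, "Fingerprint")) {
      if (isTRUE(f@normalized))
        stop("permutation tests take raw scan-level fingerprints (normalization happens after averaging)")
      f@values
    } else as.numeric(f)
  }))
  colnames(m) <- canonicalTargets()
  m
}

#' Permutation test for a fingerprint difference
#'
#' Tests whether two species' fingerprints for one seed pair differ, using
#' scan-level fingerprints as the exchangeable units. The observed
#' statistic is the cosine similarity of the two group fingerprints, each
#' formed by averaging its scan-level raw fingerprints and then min-max
#' normalizing (averaging first, normalizing second -- the same order in
#' the observed and permuted statistic). Each iteration pools the
#' `nA + nB` scan fingerprints, shuffles them without replacement into
#' pseudo-groups of the original sizes, averages, normalizes, and computes
#' the cosine. Under exchangeability this null distribution trends toward
#' 1; an observed cosine strictly below its lowest first percentile is
#' declared a significantly different fingerprint comparison.
#'
#' Iterations in which a pseudo-group average is degenerate (constant, so
#' not normalizable) are redrawn and counted; if more than 1% of
#' iterations needed a redraw the test aborts. The observed null rank is
#' recorded as an empirical p-value for reporting; the decision is the
#' percentile rule.
#'
#' @param scansA,scansB scan-level raw fingerprints per species: a
#'   scans x 8 matrix (canonical column order) or a list of raw
#'   [Fingerprint-class] objects. Both need >= 2 scans.
#' @param nIterations number of permutations (>= 100; default 10000).
#' @param rngSeed integer seed; identical inputs + seed give an identical
#'   null distribution.
#' @param q decision percentile (default 1).
#' @param seedPair character(2) labels recorded in the result.
#' @return A [PermutationResult-class].
#' @export
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(48, mean = rep(1:8, each = 6), sd = 0.1), 6, 8)
#' b <- matrix(rnorm(48, mean = rep(1:8, each = 6), sd = 0.1), 6, 8)
#' permutationTest(a, b, nIterations = 200, rngSeed = 1)
permutationTest <- function(scansA, scansB, nIterations = 10000L,
                            rngSeed = 1L, q = 1,
                            seedPair = c("seedA", "seedB")) {
  A <- fingerprintMatrix(scansA)
  B <- fingerprintMatrix(scansB)
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2L || nB < 2L)
    stop("need at least 2 scan-level fingerprints per group")
  nIterations <- as.integer(nIterations)
  if (nIterations < 100L) stop("need at least 100 iterations")

  gA <- minMax(colMeans(A))
  gB <- minMax(colMeans(B))
  if (is.null(gA) || is.null(gB))
    stop("a group-average fingerprint is constant; observed statistic undefined")
  observed <- cosineSimilarity(gA, gB)

  pooled <- rbind(A, B)
  n <- nA + nB
  idxA <- seq_len(nA)
  maxRedraw <- ceiling(0.01 * nIterations)
  nullValues <- numeric(nIterations)
  nRedraws <- 0L
  withSeed(rngSeed, {
    for (i in seq_len(nIterations)) {
      repeat {
        perm <- sample.int(n)
        mA <- minMax(.colMeans(pooled[perm[idxA], ], nA, 8L))
        mB <- minMax(.colMeans(pooled[perm[-idxA], ], nB, 8L))
        if (!is.null(mA) && !is.null(mB)) break
        nRedraws <- nRedraws + 1L
        if (nRedraws > maxRedraw)
          stop("more than 1% of permutation iterations produced degenerate (constant) pseudo-group fingerprints; aborting")
      }
      sab <- sum(mA * mB)
      nullValues[i] <- sab / sqrt(sum(mA^2) * sum(mB^2))
    }
  })
  if (nRedraws > 0L)
    message(sprintf("%d degenerate permutation iteration(s) redrawn", nRedraws))
  threshold <- lowerPercentile(nullValues, q)
  new("PermutationResult", seedPair = seedPair, observedCosine = observed,
      nullValues = nullValues, threshold = threshold,
      significant = observed < threshold,
      empiricalP = (1 + sum(nullValues <= observed)) / (1 + nIterations),
      nIterations = nIterations, rngSeed = as.integer(rngSeed),
      groupSizes = c(nA, nB), nRedraws = nRedraws)
}
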