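#' Build a raw fingerprint from an FC map
#'
#' ROI-mode maps: picks the 8 canonical target values directly. Map-mode
#' (3D) maps: averages the Fisher-z values over each target cube's member
#' voxels, ignoring `NA` (masked) voxels; if some voxels inside a target are
#' missing, a warning reports the fraction used.
#'
#' @param fc an [FCMap-class].
#' @param targets ROI data frame with the 8 canonical targets (map mode);
#'   ignored in ROI mode.
#' @param voxelMm voxel size of the map grid (map mode).
#' @return A raw [Fingerprint-class] in canonical order.
#' @export
extractFingerprint <- function(fc, targets = NULL, voxelMm = 0.5) {
  v <- fc@values
  if (is.null(dim(v))) {
    missing <- setdiff(canonicalTargets(), names(v))
    if (length(missing))
      stop("FC map lacks canonical target(s): ",
           paste(missing, collapse = ", "))
    vals <- v[canonicalTargets()]
  } else {
    stopifnot(!is.null(targets))
    d <- dim(v)
    vals <- vapply(canonicalTargets(), function(lab) {
      row <- targets[targets$label == lab, ]
      if (nrow(row) != 1L)
        stop(sprintf("target '%s' not resolvable in the ROI table", lab))
      lin <- roiLinearIndex(resolveROIVoxels(row, d, voxelMm), d)
      vv <- v[lin]
      nOK <- sum(!is.na(vv))
      if (nOK == 0L)
        stop(sprintf("target '%s' has no usable voxels in the FC map", lab))
      if (nOK < length(vv))
        warning(sprintf("target '%s': %.0f%% of voxels missing; mean over the rest",
                        lab, 100 * (1 - nOK / length(vv))))
      mean(vv, na.rm = TRUE)
    }, numeric(1))
  }
  Fingerprint(vals, seedLabel = fc@seedLabel,
              speciesLabel = fc@speciesLabel, level = fc@level,
              normalized = FALSE)
}

## Bare min-max map used in both the observed and the permuted statistic.
minMax <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(NULL)  # degenerate: no direction information
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Min-max normalize a fingerprint
#'
#' Rescales so the weakest connection maps to 0 and the strongest to 1:
#' `(f - min f) / (max f - min f)`. The comparison across species is then
#' of connectivity *pattern*, not absolute strength. Idempotent on already
#' normalized vectors; ties at the extremes are left as-is (multiple 0s or
#' 1s allowed). A constant fingerprint is rejected: it has no direction
#' information.
#'
#' @param f a raw (or already normalized) [Fingerprint-class], or a bare
#'   numeric vector.
#' @return The normalized fingerprint (same type as the input).
#' @export
#' @examples
#' normalizeFingerprint(c(2, 4, 6, 3, 5, 2.5, 3.5, 4.5))
normalizeFingerprint <- function(f) {
  if (is(f, "Fingerprint")) {
    v <- minMax(f@values)
    if (is.null(v))
      stop(sprintf("fingerprint for seed '%s' is constant; cannot normalize",
                   f@seedLabel))
    return(Fingerprint(v, seedLabel = f@seedLabel,
                       speciesLabel = f@speciesLabel, level = f@level,
                       normalized = TRUE))
  }
  v <- minMax(f)
  if (is.null(v)) stop("fingerprint is constant; cannot normalize")
  v
}

#' Cosine similarity of two fingerprints
#'
#' `(a . b) / (|a| |b|)`: 1 for identical direction, 0 for orthogonal.
#' Symmetric and scale-invariant; on min-max normalized (hence nonnegative)
#' fingerprints the value lies in [0, 1]. Both vectors must be keyed to the
#' same target order -- for `Fingerprint` inputs this is checked.
#'
#' @param a,b numeric vectors of equal length or [Fingerprint-class]
#'   objects.
#' @return Cosine similarity.
#' @export
#' @examples
#' cosineSimilarity(c(1, 1, rep(0, 6)), c(1, rep(0, 7)))  # 1/sqrt(2)
cosineSimilarity <- function(a, b) {
  if (is(a, "Fingerprint") && is(b, "Fingerprint")) {
    if (!identical(names(a@values), names(b@values)))
      stop("fingerprints are keyed to different target orders")
    a <- a@values; b <- b@values
  }
  if (length(a) != length(b)) stop("vectors have different lengths")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Cosine-similarity matrix between two species' seed sets
#'
#' Cell (i, j) is the cosine similarity between normalized group
#' fingerprint i of species A and j of species B. If scan-level raw
#' fingerprints are supplied, each cell additionally gets a
#' [permutationTest()] and the significance matrix is filled; per-cell RNG
#' seeds are derived from `rngSeed` by a fixed counter scheme.
#'
#' @param fpsA,fpsB lists of normalized group-level
#'   [Fingerprint-class] objects.
#' @param scansA,scansB optional lists (parallel to `fpsA`/`fpsB`) of
#'   scan-level raw fingerprint matrices (scans x 8) for permutation
#'   testing.
#' @param nIterations permutation iterations per cell (default 10000).
#' @param rngSeed base RNG seed for the permutation tests.
#' @return A [SimilarityMatrix-class].
#' @export
buildSimilarityMatrix <- function(fpsA, fpsB, scansA = NULL, scansB = NULL,
                                  nIterations = 10000L, rngSeed = 1L) {
  checkSet <- function(fps, which) {
    for (f in fps) {
      if (!is(f, "Fingerprint") || !isTRUE(f@normalized))
        stop("all ", which, " fingerprints must be normalized group fingerprints (mixed raw/normalized input)")
      if (!identical(f@level, "group"))
        stop("similarity matrices are built from group-level fingerprints")
    }
  }
  checkSet(fpsA, "species-A"); checkSet(fpsB, "species-B")
  labA <- vapply(fpsA, function(f) f@seedLabel, character(1))
  labB <- vapply(fpsB, function(f) f@seedLabel, character(1))
  spA <- fpsA[[1]]@speciesLabel
  spB <- fpsB[[1]]@speciesLabel
  cosM <- matrix(NA_real_, length(fpsA), length(fpsB),
                 dimnames = list(labA, labB))
  sigM <- matrix(NA, length(fpsA), length(fpsB),
                 dimnames = list(labA, labB))
  perms <- list()
  doPerm <- !is.null(scansA) && !is.null(scansB)
  cell <- 0L
  for (i in seq_along(fpsA)) {
    for (j in seq_along(fpsB)) {
      cell <- cell + 1L
      cosM[i, j] <- cosineSimilarity(fpsA[[i]], fpsB[[j]])
      if (doPerm) {
        pr <- permutationTest(scansA[[i]], scansB[[j]],
                              nIterations = nIterations,
                              rngSeed = deriveSeed(rngSeed, cell),
                              seedPair = c(labA[i], labB[j]))
        sigM[i, j] <- pr@significant
        perms[[paste(labA[i], labB[j], sep = "|")]] <- pr
      }
    }
  }
  new("SimilarityMatrix", cosine = cosM, significant = sigM,
      permResults = perms, speciesA = spA, speciesB = spB)
}

#' Seed-translation robustness sweep
#'
#' Systematically translates a seed cube about its original centroid,
#' recomputes the group fingerprint at every offset, and reports each
#' offset's cosine similarity with the centroid fingerprint -- a placement
#' sensitivity analysis. Offsets that push the seed outside the grid are
#' skipped with a message.
#'
#' @param vols list of preprocessed [VolumeSeries-class] scans.
#' @param seedROI one-row ROI data frame (cube geometry).
#' @param offsetsMm matrix or list of length-3 mm offsets (the zero offset
#'   is always included first).
#' @param targets ROI data frame with the 8 canonical targets.
#' @param speciesLabel label recorded in the fingerprints.
#' @return Data frame: offset components, the 8 normalized fingerprint
#'   values, and `cosine_with_centroid`; attribute `"skipped"` lists
#'   out-of-grid offsets.
#' @export
translationSweep <- function(vols, seedROI, offsetsMm, targets,
                             speciesLabel = "unspecified") {
  stopifnot(seedROI$geometry == "cube")
  if (is.list(offsetsMm) && !is.data.frame(offsetsMm))
    offsetsMm <- do.call(rbind, offsetsMm)
  offsetsMm <- as.matrix(offsetsMm)
  if (!any(rowSums(abs(offsetsMm)) == 0))
    offsetsMm <- rbind(c(0, 0, 0), offsetsMm)
  gs <- dim(vols[[1]]@data)[1:3]
  vox <- vols[[1]]@voxelMm
  ## target series are fixed; extract once per scan
  targetSeries <- lapply(vols, function(v) extractAllROITimeseries(v, targets))
  fpAt <- function(off) {
    roi <- seedROI
    roi$center_x_mm <- roi$center_x_mm + off[1]
    roi$center_y_mm <- roi$center_y_mm + off[2]
    roi$center_z_mm <- roi$center_z_mm + off[3]
    if (!roiInsideGrid(roi, gs, vox)) return(NULL)
    maps <- lapply(seq_along(vols), function(s) {
      series <- cbind(seed = extractROITimeseries(vols[[s]], roi),
                      targetSeries[[s]])
      seedFC(series, seedLabel = "seed", speciesLabel = speciesLabel)
    })
    normalizeFingerprint(extractFingerprint(groupFC(maps)))
  }
  rows <- list(); skipped <- list()
  centroidFp <- NULL
  for (r in seq_len(nrow(offsetsMm))) {
    off <- offsetsMm[r, ]
    fp <- fpAt(off)
    if (is.null(fp)) {
      message(sprintf("offset (%g, %g, %g) mm pushes seed '%s' outside the grid; skipped",
                      off[1], off[2], off[3], seedROI$label))
      skipped[[length(skipped) + 1L]] <- off
      next
    }
    if (is.null(centroidFp) && all(off == 0)) centroidFp <- fp
    rows[[length(rows) + 1L]] <- c(off, fp@values)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("offset_x_mm", "offset_y_mm", "offset_z_mm",
                  canonicalTargets())
  out$cosine_with_centroid <- apply(out[, canonicalTargets()], 1, function(v)
    cosineSimilarity(as.numeric(v), as.numeric(centroidFp@values)))
  attr(out, "skipped") <- skipped
  out
}
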