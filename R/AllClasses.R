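setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("numericOrArray", c("numeric", "array"))

#' VolumeSeries: a 4D resting-state image series
#'
#' Container for one registered 4D BOLD scan: an X x Y x Z x T array with
#' voxel size (mm), repetition time (s), a species-space label, and an
#' optional 3D brain mask. The mm coordinate of the voxel with 0-based index
#' `(i, j, k)` is `(i, j, k) * voxelMm`, i.e. the first voxel's center sits
#' at the origin.
#'
#' @slot data 4D numeric array (X x Y x Z x T).
#' @slot voxelMm numeric(3), voxel edge lengths in mm, all > 0.
#' @slot trSeconds positive scalar, repetition time in seconds.
#' @slot spaceLabel character scalar naming the species space.
#' @slot brainMask optional 3D logical/numeric array matching the spatial
#'   grid; `NULL` means all voxels are in-brain.
#' @export
setClass("VolumeSeries",
  representation(
    data = "array",
    voxelMm = "numeric",
    trSeconds = "numeric",
    spaceLabel = "character",
    brainMask = "arrayOrNULL"
  ),
  prototype(voxelMm = c(0.5, 0.5, 0.5), trSeconds = 1.5,
            spaceLabel = "unspecified", brainMask = NULL)
)

setValidity("VolumeSeries", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, "data must be a 4D array (X x Y x Z x T)")
  else if (d[4] < 2L)
    msg <- c(msg, "need at least 2 time points (T >= 2)")
  if (length(object@voxelMm) != 3L || any(object@voxelMm <= 0))
    msg <- c(msg, "voxelMm must be 3 positive reals")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a positive scalar")
  if (!is.null(object@brainMask)) {
    if (length(d) == 4L && !identical(dim(object@brainMask), d[1:3]))
      msg <- c(msg, "brainMask shape must match the spatial grid")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeSeries
#'
#' @param data 4D numeric array (X x Y x Z x T).
#' @param voxelMm voxel size in mm; a scalar is expanded to isotropic.
#' @param trSeconds repetition time in seconds.
#' @param spaceLabel species-space label.
#' @param brainMask optional 3D mask array.
#' @return A [VolumeSeries-class] object.
#' @export
#' @examples
#' v <- VolumeSeries(array(rnorm(4 * 4 * 3 * 10), c(4, 4, 3, 10)),
#'                   voxelMm = 0.5, trSeconds = 1.5)
#' dim(volumeData(v))
VolumeSeries <- function(data, voxelMm = 0.5, trSeconds = 1.5,
                         spaceLabel = "unspecified", brainMask = NULL) {
  if (length(voxelMm) == 1L) voxelMm <- rep(voxelMm, 3L)
  new("VolumeSeries", data = data, voxelMm = as.numeric(voxelMm),
      trSeconds = as.numeric(trSeconds), spaceLabel = spaceLabel,
      brainMask = brainMask)
}

#' @describeIn VolumeSeries the 4D data array.
#' @param x a `VolumeSeries`.
#' @export
volumeData <- function(x) x@data

#' @describeIn VolumeSeries voxel size in mm (length 3).
#' @export
voxelMm <- function(x) x@voxelMm

#' @describeIn VolumeSeries repetition time in seconds.
#' @export
trSeconds <- function(x) x@trSeconds

#' @describeIn VolumeSeries number of time points.
#' @export
nVolumes <- function(x) dim(x@data)[4]

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "VolumeSeries: %d x %d x %d grid, %d volumes, voxel %s mm, TR %.3g s, space '%s'\n",
    d[1], d[2], d[3], d[4],
    paste(format(object@voxelMm, digits = 3), collapse = " x "),
    object@trSeconds, object@spaceLabel))
})

#' SyntheticSpec: parameters of the synthetic resting-state generator
#'
#' Full description of a simulated multi-animal resting-state study for one
#' species: scan layout, acquisition-like parameters, ROI geometry, the
#' ground-truth connectivity fingerprints planted between each seed and the
#' eight canonical targets, and the noise model. Validity checks that each
#' seed has exactly one 8-vector of planted correlations in (-1, 1), that
#' the implied signal correlation matrix is positive semi-definite, and that
#' the grid fully contains every ROI cube.
#'
#' @slot speciesLabel species name used in outputs.
#' @slot nAnimals,runsPerAnimal scan layout; total scans =
#'   `nAnimals * runsPerAnimal`.
#' @slot nVolumes time points per scan (default 600).
#' @slot trSeconds repetition time in seconds (default 1.5).
#' @slot voxelMm isotropic voxel size in mm.
#' @slot gridShape integer(3) voxel grid.
#' @slot seedROIs,targetROIs ROI tables (see [roiCube()]); targets must be
#'   the 8 canonical regions in canonical order.
#' @slot groundTruthFingerprints numeric matrix, one row per seed (rownames
#'   = seed labels), 8 columns in canonical target order; entries are the
#'   planted seed-target correlations of the latent signal.
#' @slot targetCor,seedCor latent correlation among targets / among seeds
#'   (defaults 0.1), needed to close the latent covariance.
#' @slot ar1Phi lag-1 autoregressive coefficient of both signal and noise,
#'   in [0, 1).
#' @slot noiseSd observation noise SD on ROI series (latent signal has unit
#'   SD, so observed seed-target correlation is planted / (1 + noiseSd^2)).
#' @slot voxelNoiseSd independent per-voxel noise SD used by
#'   [generateVolumes()].
#' @slot signalAmplitude overall scale of the ROI courses painted into
#'   volumes; correlations are scale-invariant so this only matters for
#'   degenerate (zero-signal) cases.
#' @slot confoundAmplitude scale of the sinusoidal drift + 6 motion-like
#'   confounds mixed into the series (0 disables).
#' @slot rngSeed integer seed; identical spec + seed gives identical data.
#' @export
setClass("SyntheticSpec",
  representation(
    speciesLabel = "character",
    nAnimals = "integer",
    runsPerAnimal = "integer",
    nVolumes = "integer",
    trSeconds = "numeric",
    voxelMm = "numeric",
    gridShape = "integer",
    seedROIs = "data.frame",
    targetROIs = "data.frame",
    groundTruthFingerprints = "matrix",
    targetCor = "numeric",
    seedCor = "numeric",
    ar1Phi = "numeric",
    noiseSd = "numeric",
    voxelNoiseSd = "numeric",
    signalAmplitude = "numeric",
    confoundAmplitude = "numeric",
    rngSeed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nAnimals < 1L || object@runsPerAnimal < 1L)
    msg <- c(msg, "nAnimals and runsPerAnimal must be positive")
  if (object@nVolumes < 3L)
    msg <- c(msg, "nVolumes must be at least 3")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (object@voxelMm <= 0) msg <- c(msg, "voxelMm must be positive")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (object@ar1Phi < 0 || object@ar1Phi >= 1)
    msg <- c(msg, "ar1Phi must lie in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@confoundAmplitude < 0)
    msg <- c(msg, "confoundAmplitude must be nonnegative")
  tg <- object@targetROIs
  if (nrow(tg) != 8L || !identical(tg$label, canonicalTargets()))
    msg <- c(msg, "targetROIs must be the 8 canonical targets in canonical order")
  fp <- object@groundTruthFingerprints
  seeds <- object@seedROIs$label
  if (!identical(sort(rownames(fp)), sort(seeds)) || nrow(fp) != length(seeds))
    msg <- c(msg, "groundTruthFingerprints needs exactly one row per seed ROI")
  if (ncol(fp) != 8L)
    msg <- c(msg, "groundTruthFingerprints must have 8 columns")
  if (any(abs(fp) >= 1))
    msg <- c(msg, "planted correlations must lie in (-1, 1)")
  ## PSD check: the per-seed 9x9 latent correlation must be PSD, and so must
  ## the full (seeds + targets) matrix. No silent repair: a spec whose
  ## implied covariance is invalid is rejected outright.
  if (!length(msg)) {
    for (s in rownames(fp)) {
      sub <- latentCorrelation(fp[s, , drop = FALSE], object@targetCor,
                               object@seedCor)
      if (min(eigen(sub, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
        msg <- c(msg, sprintf(
          "planted fingerprint for seed '%s' implies a non-PSD covariance", s))
    }
    full <- latentCorrelation(fp, object@targetCor, object@seedCor)
    if (min(eigen(full, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      msg <- c(msg, "joint latent covariance over all seeds is not PSD")
    for (i in seq_len(nrow(object@seedROIs)))
      if (!roiInsideGrid(object@seedROIs[i, ], object@gridShape,
                         rep(object@voxelMm, 3)))
        msg <- c(msg, sprintf("seed ROI '%s' is not fully inside the grid",
                              object@seedROIs$label[i]))
    for (i in seq_len(nrow(tg)))
      if (!roiInsideGrid(tg[i, ], object@gridShape, rep(object@voxelMm, 3)))
        msg <- c(msg, sprintf("target ROI '%s' is not fully inside the grid",
                              tg$label[i]))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    paste0("SyntheticSpec '%s': %d animal(s) x %d run(s), T = %d, TR = %.3g s,\n",
           "  grid %s at %.3g mm, %d seed(s), AR(1) phi = %.3g, noise SD = %.3g\n"),
    object@speciesLabel, object@nAnimals, object@runsPerAnimal,
    object@nVolumes, object@trSeconds,
    paste(object@gridShape, collapse = " x "), object@voxelMm,
    nrow(object@seedROIs), object@ar1Phi, object@noiseSd))
})

#' FCMap: seed-based functional connectivity values
#'
#' Fisher-z functional connectivity of one seed, either with the 8 canonical
#' target regions (ROI mode: a named vector) or with every voxel (map mode:
#' a 3D array, masked-out voxels `NA`). Group-level maps record how many
#' scans were averaged.
#'
#' @slot values named numeric vector (ROI mode) or 3D array (map mode) of
#'   Fisher-z values.
#' @slot seedLabel,speciesLabel identity of the seed.
#' @slot level `"scan"` or `"group"`.
#' @slot nScans number of scans aggregated (1 for scan level).
#' @export
setClass("FCMap",
  representation(
    values = "numericOrArray",
    seedLabel = "character",
    speciesLabel = "character",
    level = "character",
    nScans = "integer"
  ),
  prototype(level = "scan", nScans = 1L)
)

setValidity("FCMap", function(object) {
  msg <- character()
  if (!object@level %in% c("scan", "group"))
    msg <- c(msg, "level must be 'scan' or 'group'")
  if (object@nScans < 1L) msg <- c(msg, "nScans must be >= 1")
  v <- object@values
  if (is.numeric(v) && is.null(dim(v)) && is.null(names(v)))
    msg <- c(msg, "ROI-mode values must be named by target region")
  if (length(msg)) msg else TRUE
})

#' @describeIn FCMap the Fisher-z values (named vector or 3D array).
#' @param x an `FCMap`.
#' @export
fcValues <- function(x) x@values

#' @describeIn FCMap seed label.
#' @export
seedLabel <- function(x) x@seedLabel

setMethod("show", "FCMap", function(object) {
  mode <- if (is.null(dim(object@values))) {
    sprintf("%d targets", length(object@values))
  } else {
    sprintf("%s voxel map", paste(dim(object@values), collapse = " x "))
  }
  cat(sprintf("FCMap: seed '%s' (%s), %s level, %s, %d scan(s)\n",
              object@seedLabel, object@speciesLabel, object@level, mode,
              object@nScans))
})

#' Fingerprint: interareal connectivity profile of one seed
#'
#' An ordered vector of FC values of one seed with the 8 canonical target
#' regions, at scan or group level, raw (Fisher-z scale) or min-max
#' normalized to [0, 1].
#'
#' @slot values named numeric(8), keyed to [canonicalTargets()] in order.
#' @slot seedLabel,speciesLabel identity.
#' @slot level `"scan"` or `"group"`.
#' @slot normalized logical; if `TRUE`, `min(values) == 0` and
#'   `max(values) == 1`.
#' @export
setClass("Fingerprint",
  representation(
    values = "numeric",
    seedLabel = "character",
    speciesLabel = "character",
    level = "character",
    normalized = "logical"
  ),
  prototype(level = "group", normalized = FALSE)
)

setValidity("Fingerprint", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) != 8L || !identical(names(v), canonicalTargets()))
    msg <- c(msg, "values must be a named 8-vector in canonical target order")
  if (!object@level %in% c("scan", "group"))
    msg <- c(msg, "level must be 'scan' or 'group'")
  if (isTRUE(object@normalized) && length(v) == 8L) {
    ok <- all(is.finite(v)) && abs(min(v)) < 1e-12 && abs(max(v) - 1) < 1e-12 &&
      all(v >= -1e-12 & v <= 1 + 1e-12)
    if (!ok)
      msg <- c(msg, "normalized fingerprints must span exactly [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Fingerprint
#'
#' @param values numeric(8) in canonical target order (names optional but,
#'   if present, must match [canonicalTargets()]).
#' @param seedLabel,speciesLabel identity of the seed.
#' @param level `"scan"` or `"group"`.
#' @param normalized whether `values` are already min-max normalized.
#' @return A [Fingerprint-class] object.
#' @export
Fingerprint <- function(values, seedLabel, speciesLabel, level = "group",
                        normalized = FALSE) {
  if (is.null(names(values))) {
    names(values) <- canonicalTargets()
  } else if (!identical(names(values), canonicalTargets())) {
    if (!setequal(names(values), canonicalTargets()))
      stop("fingerprint values must be named by the canonical targets")
    values <- values[canonicalTargets()]
  }
  new("Fingerprint", values = values, seedLabel = seedLabel,
      speciesLabel = speciesLabel, level = level, normalized = normalized)
}

#' @describeIn Fingerprint the named 8-vector of values.
#' @param x a `Fingerprint`.
#' @export
fpValues <- function(x) x@values

#' @describeIn Fingerprint whether the fingerprint is min-max normalized.
#' @export
isNormalized <- function(x) x@normalized

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("Fingerprint: seed '%s' (%s), %s level, %s\n",
              object@seedLabel, object@speciesLabel, object@level,
              if (object@normalized) "normalized" else "raw"))
  print(round(object@values, 4))
})

#' PermutationResult: one fingerprint-difference permutation test
#'
#' Result of the scan-level permutation test for one seed pair: observed
#' cosine similarity of the two normalized group-average fingerprints, the
#' resampling null distribution, its lowest-first-percentile threshold, and
#' the one-sided significance decision (`observed < threshold`, strict).
#'
#' @slot seedPair character(2): species-A seed, species-B seed.
#' @slot observedCosine observed cosine similarity.
#' @slot nullValues numeric(nIterations), the permutation null.
#' @slot threshold empirical 1st percentile of `nullValues` (lower order
#'   statistic at index `ceiling(n / 100)`).
#' @slot significant logical decision.
#' @slot empiricalP rank-based empirical p, `(1 + #\{null <= obs\}) / (1 + n)`,
#'   recorded for reporting only; the decision is the percentile rule.
#' @slot nIterations,rngSeed,groupSizes provenance.
#' @slot nRedraws iterations redrawn because a pseudo-group average was
#'   degenerate (constant).
#' @export
setClass("PermutationResult",
  representation(
    seedPair = "character",
    observedCosine = "numeric",
    nullValues = "numeric",
    threshold = "numeric",
    significant = "logical",
    empiricalP = "numeric",
    nIterations = "integer",
    rngSeed = "integer",
    groupSizes = "integer",
    nRedraws = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (length(object@nullValues) != object@nIterations)
    msg <- c(msg, "nullValues length must equal nIterations")
  if (!identical(object@significant,
                 object@observedCosine < object@threshold))
    msg <- c(msg, "significant must equal (observedCosine < threshold)")
  if (length(msg)) msg else TRUE
})

#' @describeIn PermutationResult observed cosine similarity.
#' @param x a `PermutationResult`.
#' @export
observedCosine <- function(x) x@observedCosine

#' @describeIn PermutationResult the permutation null distribution.
#' @export
nullValues <- function(x) x@nullValues

#' @describeIn PermutationResult the 1st-percentile decision threshold.
#' @export
permThreshold <- function(x) x@threshold

#' @describeIn PermutationResult significance decision.
#' @export
isSignificant <- function(x) x@significant

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    paste0("PermutationResult: %s vs %s\n",
           "  observed cosine %.4f, 1st-percentile threshold %.4f -> %s\n",
           "  %d iterations (seed %d), groups %d + %d, empirical p = %.4g\n"),
    object@seedPair[1], object@seedPair[2], object@observedCosine,
    object@threshold,
    if (object@significant) "significantly different" else "not significant",
    object@nIterations, object@rngSeed, object@groupSizes[1],
    object@groupSizes[2], object@empiricalP))
})

#' SimilarityMatrix: cosine similarities between two species' seed sets
#'
#' All pairwise cosine similarities between the normalized group
#' fingerprints of species A (rows) and species B (columns), with optional
#' per-cell permutation-test decisions.
#'
#' @slot cosine numeric matrix, `|seeds_A| x |seeds_B|`.
#' @slot significant logical matrix of the same shape (all `NA` when no
#'   permutation tests were run).
#' @slot permResults named list of [PermutationResult-class] objects, keyed
#'   `"<seedA>|<seedB>"`; every significant cell has one.
#' @slot speciesA,speciesB species labels.
#' @export
setClass("SimilarityMatrix",
  representation(
    cosine = "matrix",
    significant = "matrix",
    permResults = "list",
    speciesA = "character",
    speciesB = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@cosine), dim(object@significant)))
    msg <- c(msg, "cosine and significant must have the same shape")
  sig <- object@significant
  if (any(sig %in% TRUE)) {
    keys <- outer(rownames(sig), colnames(sig), paste, sep = "|")
    need <- keys[which(sig)]
    if (!all(need %in% names(object@permResults)))
      msg <- c(msg, "every significant cell needs an attached PermutationResult")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimilarityMatrix the cosine matrix.
#' @param x a `SimilarityMatrix`.
#' @export
cosineValues <- function(x) x@cosine

#' @describeIn SimilarityMatrix the logical significance matrix.
#' @export
significanceMatrix <- function(x) x@significant

#' @describeIn SimilarityMatrix the list of per-cell permutation results.
#' @export
permResults <- function(x) x@permResults

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %s (%d seeds) x %s (%d seeds), %d cells\n",
              object@speciesA, nrow(object@cosine), object@speciesB,
              ncol(object@cosine), length(object@cosine)))
  print(round(object@cosine, 3))
  if (any(!is.na(object@significant))) {
    cat(sprintf("significantly different cells: %d / %d\n",
                sum(object@significant, na.rm = TRUE),
                length(object@significant)))
  }
})
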