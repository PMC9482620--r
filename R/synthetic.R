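## Latent signal model: per scan, the (seeds + 8 targets) ROI signals are
## jointly Gaussian with unit variance, correlation between seed s and
## target t given by the planted fingerprint, a fixed small correlation
## among targets and among seeds (the paper-facing structure only pins the
## seed row; the rest must be closed to make the covariance well-defined),
## AR(1) temporal autocorrelation, plus independent AR(1) observation noise.

latentCorrelation <- function(fingerprints, targetCor, seedCor) {
  nS <- nrow(fingerprints)
  nT <- ncol(fingerprints)
  n <- nS + nT
  R <- matrix(0, n, n)
  R[seq_len(nS), seq_len(nS)] <- seedCor
  R[nS + seq_len(nT), nS + seq_len(nT)] <- targetCor
  R[seq_len(nS), nS + seq_len(nT)] <- fingerprints
  R[nS + seq_len(nT), seq_len(nS)] <- t(fingerprints)
  diag(R) <- 1
  labels <- c(rownames(fingerprints), colnames(fingerprints))
  dimnames(R) <- list(labels, labels)
  R
}

## Stationary unit-variance AR(1) colored noise, one column per series.
## x_1 = e_1, x_t = phi x_{t-1} + sqrt(1 - phi^2) e_t.
ar1Series <- function(nT, nCol, phi) {
  e <- matrix(rnorm(nT * nCol), nT, nCol)
  if (phi == 0) return(e)
  inn <- e * sqrt(1 - phi^2)
  inn[1, ] <- e[1, ]
  out <- stats::filter(inn, phi, method = "recursive")
  matrix(as.numeric(out), nT, nCol)
}

## Matrix square root via eigendecomposition (tolerates semi-definiteness,
## unlike chol); deterministic for a fixed input.
corTransform <- function(R) {
  es <- eigen(R, symmetric = TRUE)
  ev <- pmax(es$values, 0)
  es$vectors %*% (sqrt(ev) * t(es$vectors))
}

## Smooth confound set: 1 slow sinusoidal drift + 6 motion-like regressors
## built from low-frequency sinusoids with random phases, standardized.
makeConfounds <- function(nT, trSeconds) {
  tt <- seq_len(nT) * trSeconds
  span <- nT * trSeconds
  drift <- sin(2 * pi * tt / span)
  motion <- sapply(seq_len(6), function(k) {
    f <- runif(1, 0.5, 3) / span
    ph <- runif(1, 0, 2 * pi)
    sin(2 * pi * f * tt + ph) + 0.3 * sin(2 * pi * 2.7 * f * tt + 2 * ph)
  })
  cf <- cbind(drift = drift, motion)
  colnames(cf) <- c("drift", paste0("motion_", 1:6))
  scale(cf)[, , drop = TRUE]
}

#' Build a synthetic-study specification
#'
#' Constructs a validated [SyntheticSpec-class]. Defaults emulate the
#' acquisition regime the pipeline targets: 600 volumes at TR 1.5 s,
#' isotropic 0.5 mm voxels, 5 animals with 1 run each, AR(1) temporal
#' autocorrelation phi = 0.3, and observation noise SD 0.5 (chosen so a
#' single-scan seed-target correlation estimate has standard error of about
#' 0.04 at T = 600). If `seedROIs`/`targetROIs` are omitted, cubic ROIs are
#' laid out automatically on a lattice inside the grid.
#'
#' @param speciesLabel species name.
#' @param groundTruthFingerprints numeric matrix (seeds x 8) of planted
#'   latent seed-target correlations, rownames = seed labels; a plain
#'   8-vector is treated as a single seed named `"seed1"`.
#' @param nAnimals,runsPerAnimal scan layout (total scans = product).
#' @param nVolumes,trSeconds,voxelMm,gridShape acquisition-like geometry.
#' @param seedROIs,targetROIs optional ROI tables; autogenerated when `NULL`.
#' @param edgeMm cube edge for autogenerated ROIs.
#' @param targetCor,seedCor latent correlation among targets / among seeds.
#' @param ar1Phi,noiseSd,voxelNoiseSd,signalAmplitude,confoundAmplitude
#'   noise model; see [SyntheticSpec-class].
#' @param rngSeed integer RNG seed.
#' @return A validated [SyntheticSpec-class].
#' @export
#' @examples
#' sp <- syntheticSpec("ratlike", exampleFingerprint(), nVolumes = 100)
#' sp
syntheticSpec <- function(speciesLabel, groundTruthFingerprints,
                          nAnimals = 5L, runsPerAnimal = 1L,
                          nVolumes = 600L, trSeconds = 1.5, voxelMm = 0.5,
                          gridShape = c(16L, 16L, 10L),
                          seedROIs = NULL, targetROIs = NULL, edgeMm = 1.5,
                          targetCor = 0.1, seedCor = 0.1,
                          ar1Phi = 0.3, noiseSd = 0.5, voxelNoiseSd = 0.5,
                          signalAmplitude = 1, confoundAmplitude = 0.25,
                          rngSeed = 1L) {
  fp <- groundTruthFingerprints
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1,
                                     dimnames = list("seed1", NULL))
  colnames(fp) <- canonicalTargets()
  if (is.null(rownames(fp))) rownames(fp) <- paste0("seed", seq_len(nrow(fp)))
  if (is.null(seedROIs) || is.null(targetROIs)) {
    auto <- latticeROIs(nSeeds = nrow(fp), seedLabels = rownames(fp),
                        gridShape = gridShape, voxelMm = voxelMm,
                        edgeMm = edgeMm, space = speciesLabel)
    if (is.null(seedROIs)) seedROIs <- auto[auto$role == "seed", ]
    if (is.null(targetROIs)) targetROIs <- auto[auto$role == "target", ]
  }
  rownames(seedROIs) <- NULL
  rownames(targetROIs) <- NULL
  new("SyntheticSpec", speciesLabel = speciesLabel,
      nAnimals = as.integer(nAnimals),
      runsPerAnimal = as.integer(runsPerAnimal),
      nVolumes = as.integer(nVolumes), trSeconds = trSeconds,
      voxelMm = voxelMm, gridShape = as.integer(gridShape),
      seedROIs = seedROIs, targetROIs = targetROIs,
      groundTruthFingerprints = fp, targetCor = targetCor, seedCor = seedCor,
      ar1Phi = ar1Phi, noiseSd = noiseSd, voxelNoiseSd = voxelNoiseSd,
      signalAmplitude = signalAmplitude,
      confoundAmplitude = confoundAmplitude, rngSeed = as.integer(rngSeed))
}

#' A plausible example ground-truth fingerprint
#'
#' An 8-vector of latent seed-target correlations with a frontoparietal-like
#' profile (strong PCC/PPC coupling), usable as a planted ground truth.
#'
#' @param rotate integer; circularly shifts the profile to derive distinct
#'   seeds from one template.
#' @return Named numeric(8).
#' @export
exampleFingerprint <- function(rotate = 0L) {
  base <- c(M1 = 0.35, Ins = 0.25, S1 = 0.30, PCC = 0.60, PPC = 0.65,
            Str = 0.40, Pul = 0.45, SC = 0.20)
  v <- base
  if (rotate != 0L) {
    idx <- ((seq_len(8) - 1 + rotate) %% 8) + 1
    v <- setNames(base[idx], canonicalTargets())
  }
  v
}

#' Lay ROI cubes out on a lattice inside a grid
#'
#' Places `nSeeds` seed cubes followed by the 8 canonical target cubes at
#' well-separated lattice positions, for synthetic studies where anatomy is
#' irrelevant but geometry must be valid.
#'
#' @param nSeeds number of seed cubes.
#' @param seedLabels seed names (default `seed1..seedN`).
#' @param gridShape integer(3) voxel grid.
#' @param voxelMm isotropic voxel size (mm).
#' @param edgeMm cube edge (mm).
#' @param space species-space label.
#' @return ROI data frame with `nSeeds + 8` rows.
#' @export
latticeROIs <- function(nSeeds, seedLabels = paste0("seed", seq_len(nSeeds)),
                        gridShape = c(16L, 16L, 10L), voxelMm = 0.5,
                        edgeMm = 1.5, space = "synthetic") {
  edgeVox <- ceiling(edgeMm / voxelMm)
  pitch <- edgeVox + 2L          # two clear voxels between cubes
  start <- floor(edgeVox / 2) + 1L
  centersAxis <- lapply(1:3, function(a) {
    nPos <- max(floor((gridShape[a] - 1L - start) / pitch) + 1L, 1L)
    seq.int(start, by = pitch, length.out = nPos)
  })
  pos <- expand.grid(i = centersAxis[[1]], j = centersAxis[[2]],
                     k = centersAxis[[3]])
  need <- nSeeds + 8L
  if (nrow(pos) < need)
    stop(sprintf("grid %s too small for %d ROI cubes of edge %g mm",
                 paste(gridShape, collapse = "x"), need, edgeMm))
  labels <- c(seedLabels, canonicalTargets())
  roles <- c(rep("seed", nSeeds), rep("target", 8L))
  out <- do.call(rbind, lapply(seq_len(need), function(r) {
    roiCube(labels[r], as.numeric(pos[r, ]) * voxelMm, edgeMm,
            role = roles[r], space = space)
  }))
  rownames(out) <- NULL
  out
}

#' Generate ROI-level resting-state time series
#'
#' Draws, for every scan of the study described by `spec`, jointly Gaussian
#' latent ROI signals with the planted seed-target correlation structure,
#' AR(1) temporal autocorrelation, AR(1) observation noise, and (if
#' `confoundAmplitude > 0`) a sinusoidal drift plus six smooth motion-like
#' confounds mixed into every ROI with random loadings. Identical spec +
#' seed gives identical output.
#'
#' With observation noise of standard deviation `s` on unit-variance latent
#' signals, the expected observed seed-target correlation is the planted
#' value divided by `1 + s^2`; tests against planted values use `noiseSd = 0`
#' or account for this attenuation.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List of scans; each scan is a list with elements `series`
#'   (T x nROI numeric matrix, columns named seed labels then canonical
#'   targets), `confounds` (T x 7 data frame), `animal`, `run`, `species`.
#' @export
#' @examples
#' sp <- syntheticSpec("demo", exampleFingerprint(), nAnimals = 2,
#'                     nVolumes = 120, rngSeed = 7)
#' scans <- generateROITimeseries(sp)
#' cor(scans[[1]]$series[, "seed1"], scans[[1]]$series[, "PPC"])
generateROITimeseries <- function(spec) {
  validObject(spec)
  fp <- spec@groundTruthFingerprints
  R <- latentCorrelation(fp, spec@targetCor, spec@seedCor)
  A <- corTransform(R)
  nROI <- ncol(R)
  nT <- spec@nVolumes
  labels <- colnames(R)
  withSeed(spec@rngSeed, {
    scans <- list()
    for (animal in seq_len(spec@nAnimals)) {
      for (run in seq_len(spec@runsPerAnimal)) {
        latent <- ar1Series(nT, nROI, spec@ar1Phi) %*% A
        noise <- ar1Series(nT, nROI, spec@ar1Phi) * spec@noiseSd
        series <- spec@signalAmplitude * (latent + noise)
        cf <- makeConfounds(nT, spec@trSeconds)
        if (spec@confoundAmplitude > 0) {
          loadings <- matrix(rnorm(ncol(cf) * nROI), ncol(cf), nROI)
          series <- series + spec@confoundAmplitude * (cf %*% loadings)
        }
        colnames(series) <- labels
        scans[[length(scans) + 1L]] <- list(
          series = series,
          confounds = as.data.frame(cf),
          animal = animal, run = run, species = spec@speciesLabel)
      }
    }
    scans
  })
}

#' Generate synthetic 4D volumes
#'
#' Renders the ROI-level series of [generateROITimeseries()] into 4D
#' volumes: every voxel whose center falls inside an ROI cube carries that
#' ROI's time course plus independent per-voxel noise; all other voxels
#' carry pure per-voxel noise. The ROI sidecar describing the painted
#' geometry is attached so the downstream pipeline can re-extract the
#' regions.
#'
#' @param spec a [SyntheticSpec-class].
#' @return List with elements `volumes` (list of [VolumeSeries-class], one
#'   per scan), `rois` (ROI sidecar data frame), `scans` (the underlying
#'   ROI-level scan list, for reference), `spec`.
#' @export
generateVolumes <- function(spec) {
  validObject(spec)
  scans <- generateROITimeseries(spec)
  rois <- rbind(spec@seedROIs, spec@targetROIs)
  vox3 <- rep(spec@voxelMm, 3)
  gs <- spec@gridShape
  nVox <- prod(gs)
  nT <- spec@nVolumes
  linIdx <- lapply(seq_len(nrow(rois)), function(r) {
    roiLinearIndex(resolveROIVoxels(rois[r, ], gs, vox3), gs)
  })
  volumes <- withSeed(deriveSeed(spec@rngSeed, 1L), {
    lapply(scans, function(scan) {
      flat <- if (spec@voxelNoiseSd > 0) {
        matrix(rnorm(nVox * nT, sd = spec@voxelNoiseSd), nVox, nT)
      } else {
        matrix(0, nVox, nT)
      }
      for (r in seq_len(nrow(rois))) {
        lin <- linIdx[[r]]
        flat[lin, ] <- flat[lin, , drop = FALSE] +
          matrix(scan$series[, rois$label[r]], length(lin), nT, byrow = TRUE)
      }
      VolumeSeries(array(flat, c(gs, nT)), voxelMm = spec@voxelMm,
                   trSeconds = spec@trSeconds, spaceLabel = spec@speciesLabel)
    })
  })
  list(volumes = volumes, rois = rois, scans = scans, spec = spec)
}

#' Read / write ROI time-series tables
#'
#' TSV with one column per ROI and one row per volume.
#'
#' @param path file path.
#' @return `readROISeries` returns a numeric matrix with column names.
#' @export
readROISeries <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' @rdname readROISeries
#' @param series T x nROI numeric matrix with column names.
#' @export
writeROISeries <- function(series, path) {
  write.table(formatReal(series), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
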