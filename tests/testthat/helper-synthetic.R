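# Shared fixtures for the test suite; everything is generated in code.

# A small, fast spec: clean signal (no observation noise, no confounds)
# unless overridden.
cleanSpec <- function(nVolumes = 400, nAnimals = 2, rngSeed = 42, ...) {
  syntheticSpec("testspecies", exampleFingerprint(),
                nAnimals = nAnimals, nVolumes = nVolumes,
                noiseSd = 0, confoundAmplitude = 0, voxelNoiseSd = 0,
                rngSeed = rngSeed, ...)
}

# Scan-level fingerprint matrices drawn around a common mean profile
# (fingerprints on the Fisher-z scale, sd ~ the single-scan estimation SE).
sampleScanFingerprints <- function(n, mu, sd = 0.1) {
  matrix(rnorm(n * 8, mean = rep(mu, each = n), sd = sd), n, 8,
         dimnames = list(NULL, canonicalTargets()))
}

# A second ground-truth profile at a planted angle (degrees) from `mu`,
# rotated within the plane spanned by mu and an orthogonal direction,
# preserving the norm.
rotatedProfile <- function(mu, angleDeg) {
  w <- c(0.6, -0.3, 0.5, -0.4, 0.35, -0.5, 0.3, -0.25)
  w <- w - sum(w * mu) / sum(mu^2) * mu      # orthogonalize against mu
  w <- w / sqrt(sum(w^2)) * sqrt(sum(mu^2))  # same norm
  th <- angleDeg * pi / 180
  cos(th) * mu + sin(th) * w
}

# Brute-force discrete Gaussian smoothing of a 1D sequence with
# half-sample symmetric reflection (independent oracle for smoothGaussian).
bruteSmooth1D <- function(x, sigmaVox) {
  n <- length(x)
  radius <- max(1L, ceiling(4 * sigmaVox))
  offs <- (-radius):radius
  w <- exp(-offs^2 / (2 * sigmaVox^2)); w <- w / sum(w)
  vapply(seq_len(n), function(i) {
    acc <- 0
    for (d in seq_along(offs)) {
      j <- i - 1L + offs[d]
      while (j < 0 || j >= n) {
        if (j < 0) j <- -1L - j
        if (j >= n) j <- 2L * n - 1L - j
      }
      acc <- acc + w[d] * x[j + 1L]
    }
    acc
  }, numeric(1))
}

# FFT amplitude of a series at frequency f0 (Hz) given sampling period tr.
fftAmplitude <- function(x, f0, tr) {
  n <- length(x)
  bin <- round(f0 * n * tr) + 1L
  abs(fft(x))[bin] / (n / 2)
}

# Write a small ROI-mode synthetic study to disk and return its config.
writeStudy <- function(dir, speciesLabels = c("specA", "specB"),
                       nSeeds = c(2, 2), nScans = 3, nVolumes = 150,
                       seedBase = 70) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  speciesBlocks <- lapply(seq_along(speciesLabels), function(si) {
    lab <- speciesLabels[si]
    mu <- atanh(0.7 * as.numeric(exampleFingerprint()))
    # distinct seeds: small rotations of one profile, mapped back to (-1, 1)
    fp <- do.call(rbind, lapply(seq_len(nSeeds[si]), function(k)
      tanh(rotatedProfile(mu, 10 * k))))
    rownames(fp) <- paste0(lab, "_seed", seq_len(nSeeds[si]))
    sp <- syntheticSpec(lab, fp, nAnimals = nScans, nVolumes = nVolumes,
                        noiseSd = 0.3, confoundAmplitude = 0.2,
                        rngSeed = seedBase + si)
    scans <- generateROITimeseries(sp)
    scanBlocks <- lapply(seq_along(scans), function(ci) {
      roiPath <- file.path(dir, sprintf("%s_scan%d.tsv", lab, ci))
      cfPath <- file.path(dir, sprintf("%s_scan%d_confounds.tsv", lab, ci))
      writeROISeries(scans[[ci]]$series, roiPath)
      writeConfounds(scans[[ci]]$confounds, cfPath)
      list(roi_table = roiPath, confounds = cfPath, tr_seconds = 1.5)
    })
    list(label = lab, seeds = as.list(rownames(fp)), scans = scanBlocks)
  })
  list(seed = 1234, output_dir = file.path(dir, "out"),
       permutation = list(enabled = TRUE, n_iterations = 200),
       species = speciesBlocks)
}
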