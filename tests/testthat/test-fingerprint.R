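test_that("min-max normalization matches the affine map, is idempotent, rejects constants", {
  v <- c(2, 4, 6, 3, 5, 2.5, 3.5, 4.5)
  expect_equal(normalizeFingerprint(v),
               c(0, 0.5, 1, 0.25, 0.75, 0.125, 0.375, 0.625),
               tolerance = 1e-15)
  expect_equal(normalizeFingerprint(normalizeFingerprint(v)),
               normalizeFingerprint(v), tolerance = 1e-15)
  expect_error(normalizeFingerprint(rep(3, 8)), "constant")

  fp <- Fingerprint(v, "s", "sp")
  nf <- normalizeFingerprint(fp)
  expect_true(isNormalized(nf))
  expect_identical(unname(range(fpValues(nf))), c(0, 1))
  # ties at the extremes are left as-is
  expect_equal(unname(normalizeFingerprint(c(1, 1, 2, 3, 3, 2, 1, 3))),
               c(0, 0, 0.5, 1, 1, 0.5, 0, 1))
})

test_that("cosine similarity matches the explicit formula and its invariances", {
  e1 <- c(1, rep(0, 7)); e2 <- c(0, 1, rep(0, 6))
  expect_equal(cosineSimilarity(e1, e1), 1)
  expect_equal(cosineSimilarity(e1, e2), 0)
  expect_equal(cosineSimilarity(c(1, 1, rep(0, 6)), e1), 1 / sqrt(2),
               tolerance = 1e-12)
  set.seed(40)
  for (i in 1:20) {
    a <- runif(8); b <- runif(8)
    expect_equal(cosineSimilarity(a, b),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
    expect_equal(cosineSimilarity(a, b), cosineSimilarity(b, a))
    expect_equal(cosineSimilarity(0.37 * a, b), cosineSimilarity(a, b),
                 tolerance = 1e-12)
  }
  expect_error(cosineSimilarity(rep(0, 8), e1), "zero vector")
})

test_that("cosine on normalized fingerprints lies in [0, 1]", {
  set.seed(41)
  for (i in 1:50) {
    a <- normalizeFingerprint(rnorm(8))
    b <- normalizeFingerprint(rnorm(8))
    cs <- cosineSimilarity(a, b)
    expect_gte(cs, 0); expect_lte(cs, 1)
  }
})

test_that("cosine is invariant to consistent target reordering but not inconsistent", {
  set.seed(42)
  a <- runif(8); b <- runif(8)
  perm <- sample(8)
  expect_equal(cosineSimilarity(a[perm], b[perm]), cosineSimilarity(a, b),
               tolerance = 1e-12)
  # shuffling only one vector changes the value (canonical-order contract)
  expect_false(isTRUE(all.equal(cosineSimilarity(a[perm], b),
                                cosineSimilarity(a, b))))
  # the canonical-order contract is enforced at construction time
  expect_error(new("Fingerprint", values = setNames(b, rev(canonicalTargets())),
                   seedLabel = "y", speciesLabel = "spB", level = "group",
                   normalized = FALSE),
               "canonical")
})

test_that("extractFingerprint picks canonical targets in order; constant maps give constant prints", {
  v <- setNames(rnorm(8), sample(canonicalTargets()))
  fc <- new("FCMap", values = v, seedLabel = "s", speciesLabel = "sp",
            level = "group", nScans = 3L)
  fp <- extractFingerprint(fc)
  expect_identical(names(fpValues(fp)), canonicalTargets())
  expect_equal(unname(fpValues(fp)), unname(v[canonicalTargets()]))

  const <- new("FCMap", values = setNames(rep(0.4, 8), canonicalTargets()),
               seedLabel = "s", speciesLabel = "sp", level = "scan",
               nScans = 1L)
  expect_true(all(fpValues(extractFingerprint(const)) == 0.4))

  missing <- new("FCMap", values = setNames(rnorm(7), canonicalTargets()[1:7]),
                 seedLabel = "s", speciesLabel = "sp", level = "scan",
                 nScans = 1L)
  expect_error(extractFingerprint(missing), "SC")
})

test_that("map-mode fingerprint entries equal brute-force voxel means over target cubes", {
  set.seed(43)
  gs <- c(12, 12, 8)
  rois <- latticeROIs(nSeeds = 1, gridShape = gs, voxelMm = 0.5,
                      edgeMm = 1.0)
  zmap <- array(rnorm(prod(gs)), gs)
  fc <- new("FCMap", values = zmap, seedLabel = "seed1",
            speciesLabel = "sp", level = "group", nScans = 5L)
  fp <- extractFingerprint(fc, targets = rois, voxelMm = 0.5)
  for (lab in canonicalTargets()) {
    idx <- resolveROIVoxels(rois[rois$label == lab, ], gs, 0.5)
    acc <- 0
    for (r in seq_len(nrow(idx)))
      acc <- acc + zmap[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1]
    expect_equal(unname(fpValues(fp)[lab]), acc / nrow(idx),
                 tolerance = 1e-12)
  }
  # NA voxels inside a target: mean over the present ones, with a warning
  idx <- resolveROIVoxels(rois[rois$label == "M1", ], gs, 0.5)
  zmap2 <- zmap
  zmap2[idx[1, 1] + 1, idx[1, 2] + 1, idx[1, 3] + 1] <- NA
  fc2 <- new("FCMap", values = zmap2, seedLabel = "seed1",
             speciesLabel = "sp", level = "group", nScans = 5L)
  expect_warning(fp2 <- extractFingerprint(fc2, targets = rois,
                                           voxelMm = 0.5), "M1")
  expect_false(is.na(fpValues(fp2)["M1"]))
})

test_that("similarity matrices have |A| x |B| cells and a unit self-diagonal", {
  set.seed(44)
  mkFp <- function(lab, sp) normalizeFingerprint(
    Fingerprint(rnorm(8), lab, sp))
  fpsA <- lapply(paste0("a", 1:5), mkFp, sp = "A")
  fpsB <- lapply(paste0("b", 1:8), mkFp, sp = "B")
  sim <- buildSimilarityMatrix(fpsA, fpsB)
  expect_identical(dim(cosineValues(sim)), c(5L, 8L))
  self <- buildSimilarityMatrix(fpsA, fpsA)
  expect_equal(unname(diag(cosineValues(self))), rep(1, 5), tolerance = 1e-12)
  # mixed raw/normalized input is rejected
  raw <- Fingerprint(rnorm(8), "r", "A")
  expect_error(buildSimilarityMatrix(c(fpsA, list(raw)), fpsB), "normalized")
})

test_that("planted fingerprint angle degrades estimated cosine monotonically", {
  set.seed(45)
  mu <- as.numeric(atanh(exampleFingerprint()))
  angles <- c(5, 25, 45, 65, 85)
  meanCos <- sapply(angles, function(ang) {
    muB <- rotatedProfile(mu, ang)
    mean(replicate(20, {
      a <- colMeans(sampleScanFingerprints(6, mu, sd = 0.1))
      b <- colMeans(sampleScanFingerprints(6, muB, sd = 0.1))
      cosineSimilarity(normalizeFingerprint(a), normalizeFingerprint(b))
    }))
  })
  rho <- cor(meanCos, angles, method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("translation sweep: zero offset is cosine 1; within-cube offsets stay >= 0.99; noise offsets degrade", {
  fp <- matrix(0.8 * c(0.7, 0.2, 0.5, 0.6, 0.65, 0.3, 0.4, 0.25), 1, 8,
               dimnames = list("s", canonicalTargets()))
  sp <- syntheticSpec("sweep", fp, nAnimals = 3, nVolumes = 300,
                      noiseSd = 0.2, voxelNoiseSd = 0.2,
                      confoundAmplitude = 0, rngSeed = 55)
  out <- generateVolumes(sp)
  seedROI <- out$rois[out$rois$label == "s", ]
  targets <- out$rois[out$rois$role == "target", ]
  offs <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0, 0.5, 0), c(0, 0, 0.5))
  sw <- translationSweep(out$volumes, seedROI, offs, targets,
                         speciesLabel = "sweep")
  expect_equal(sw$cosine_with_centroid[1], 1, tolerance = 1e-12)
  expect_true(all(sw$cosine_with_centroid >= 0.99))

  # an offset pushing the seed out of the grid is skipped with a message
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_message(sw2 <- translationSweep(out$volumes, seedROI, far, targets),
                 "outside the grid")
  expect_identical(nrow(sw2), 1L)
  expect_length(attr(sw2, "skipped"), 1)
})
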