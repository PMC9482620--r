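test_that("pearsonR matches a from-definition two-pass oracle and handles edge cases", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  twoPass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(pearsonR(x, y), twoPass(x, y), tolerance = 1e-12)
  expect_equal(pearsonR(x, x), 1, tolerance = 1e-15)
  expect_equal(pearsonR(x, -x), -1, tolerance = 1e-15)
  expect_equal(pearsonR(x, y), pearsonR(y, x))
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(pearsonR(a, b), twoPass(a, b), tolerance = 1e-12)
  }
  expect_error(pearsonR(rep(1, 5), rnorm(5)), "first series")
  expect_error(pearsonR(rnorm(5), rep(2, 5)), "second series")
  expect_error(pearsonR(1:2, 2:3), "at least 3")
})

test_that("fisherZ matches the log identity, is odd, strictly increasing, and clamps", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  expect_equal(fisherZ(-0.5), -fisherZ(0.5), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_warning(zmax <- fisherZ(1), "clamped")
  expect_equal(zmax, atanh(1 - 1e-7))
})

test_that("seedFC on white noise stays within the Fisher-z null band; identical series clamp", {
  set.seed(30)
  nT <- 600
  series <- cbind(seed = rnorm(nT),
                  matrix(rnorm(nT * 8), nT, 8,
                         dimnames = list(NULL, canonicalTargets())))
  fc <- seedFC(series, "seed", speciesLabel = "noise")
  # 8 independent null z values; bound at 4 SE so the joint event is
  # overwhelmingly likely under the null (and pinned by the fixed seed)
  expect_true(all(abs(fcValues(fc)) < 4 / sqrt(nT - 3)))

  dup <- series
  dup[, "M1"] <- dup[, "seed"]
  expect_warning(fc2 <- seedFC(dup, "seed"), "clamped")
  expect_equal(unname(fcValues(fc2)["M1"]), atanh(1 - 1e-7))
})

test_that("seedFC recovers a planted correlation across scans within 2 SE", {
  set.seed(31)
  nT <- 600; nScans <- 50; r <- 0.6
  zs <- replicate(nScans, {
    s <- rnorm(nT)
    y <- r * s + sqrt(1 - r^2) * rnorm(nT)
    series <- cbind(seed = s,
                    matrix(rnorm(nT * 7), nT, 7,
                           dimnames = list(NULL, canonicalTargets()[1:7])))
    series <- cbind(series, SC = y)
    fcValues(seedFC(series, "seed"))["SC"]
  })
  se <- 1 / sqrt(nT - 3) / sqrt(nScans)
  expect_lt(abs(mean(zs) - atanh(r)), 2 * se + 0.002)  # + tiny z-mean bias slack
})

test_that("seed FC is invariant to common positive affine rescaling", {
  set.seed(32)
  series <- cbind(seed = rnorm(100),
                  matrix(rnorm(800), 100, 8,
                         dimnames = list(NULL, canonicalTargets())))
  fc1 <- seedFC(series, "seed")
  fc2 <- seedFC(3.5 * series + 2, "seed")
  expect_equal(fcValues(fc1), fcValues(fc2), tolerance = 1e-12)
})

test_that("constant targets become NA with a warning; constant seeds error", {
  set.seed(33)
  series <- cbind(seed = rnorm(50),
                  matrix(rnorm(400), 50, 8,
                         dimnames = list(NULL, canonicalTargets())))
  series[, "Pul"] <- 1
  expect_warning(fc <- seedFC(series, "seed"), "1 constant target")
  expect_true(is.na(fcValues(fc)["Pul"]))
  series[, "seed"] <- 0
  expect_error(seedFC(series, "seed"), "constant")
})

test_that("groupFC is the exact elementwise mean, identity on one scan, zero on z/-z", {
  mkMap <- function(v) new("FCMap", values = setNames(v, canonicalTargets()),
                           seedLabel = "s", speciesLabel = "sp",
                           level = "scan", nScans = 1L)
  set.seed(34)
  maps <- lapply(1:10, function(i) mkMap(rnorm(8)))
  g <- groupFC(maps)
  oracle <- setNames(numeric(8), canonicalTargets())
  for (m in maps) oracle <- oracle + fcValues(m)
  oracle <- oracle / 10
  expect_identical(fcValues(g), oracle)
  expect_identical(g@nScans, 10L)
  expect_identical(g@level, "group")

  single <- groupFC(maps[1])
  expect_identical(fcValues(single), fcValues(maps[[1]]))

  z <- rnorm(8)
  expect_equal(unname(fcValues(groupFC(list(mkMap(z), mkMap(-z))))),
               rep(0, 8))
})

test_that("groupFC rejects mixed seeds or mismatched grids", {
  a <- new("FCMap", values = setNames(rnorm(8), canonicalTargets()),
           seedLabel = "s1", speciesLabel = "sp", level = "scan", nScans = 1L)
  b <- new("FCMap", values = setNames(rnorm(8), canonicalTargets()),
           seedLabel = "s2", speciesLabel = "sp", level = "scan", nScans = 1L)
  expect_error(groupFC(list(a, b)), "mixed seeds")
  c1 <- new("FCMap", values = array(rnorm(8), c(2, 2, 2)), seedLabel = "s1",
            speciesLabel = "sp", level = "scan", nScans = 1L)
  expect_error(groupFC(list(a, c1)), "mismatched")
})

test_that("group FC standard error shrinks as 1/sqrt(scans)", {
  set.seed(35)
  nRep <- 200
  seAt <- sapply(c(2, 5, 10), function(S) {
    sd(replicate(nRep, mean(rnorm(S, sd = 0.3))))
  })
  ratio <- seAt / (0.3 / sqrt(c(2, 5, 10)))
  expect_true(all(abs(ratio - 1) < 0.2))
})

test_that("map-mode seedFC produces a masked 3D z map consistent with ROI extraction", {
  fp <- matrix(c(0.7, rep(0.15, 7)), 1, 8,
               dimnames = list("s", canonicalTargets()))
  sp <- syntheticSpec("map", fp, nAnimals = 1, nVolumes = 200,
                      noiseSd = 0, voxelNoiseSd = 0.3, confoundAmplitude = 0,
                      rngSeed = 17)
  out <- generateVolumes(sp)
  v <- out$volumes[[1]]
  seedROI <- out$rois[out$rois$label == "s", ]
  fc <- seedFC(v, seedROI = seedROI, speciesLabel = "map")
  expect_identical(dim(fcValues(fc)), dim(volumeData(v))[1:3])
  fpGot <- extractFingerprint(fc, targets = out$rois, voxelMm = 0.5)
  expect_s4_class(fpGot, "Fingerprint")
  # M1 carries the planted 0.7-correlated course; the z there must exceed
  # the other targets (which share only targetCor = 0.1)
  expect_true(which.max(fpValues(fpGot)) == 1L)
})
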