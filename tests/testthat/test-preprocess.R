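test_that("smoothing leaves spatially constant volumes unchanged and preserves mass", {
  v <- VolumeSeries(array(3.7, c(8, 8, 6, 3)), voxelMm = 0.5)
  sm <- smoothGaussian(v, 1.0)
  expect_equal(volumeData(sm), volumeData(v), tolerance = 1e-12)

  set.seed(2)
  v2 <- VolumeSeries(array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2)),
                     voxelMm = 0.5)
  sm2 <- smoothGaussian(v2, 1.2)
  for (t in 1:2)
    expect_equal(sum(volumeData(sm2)[, , , t]),
                 sum(volumeData(v2)[, , , t]), tolerance = 1e-6)
})

test_that("an impulse is smoothed exactly as the brute-force separable kernel", {
  arr <- array(0, c(9, 9, 7, 2))
  arr[5, 5, 4, ] <- 1
  v <- VolumeSeries(arr, voxelMm = 0.5)
  sm <- smoothGaussian(v, 1.0)
  sigmaVox <- 1.0 / (2 * sqrt(2 * log(2))) / 0.5
  # separable oracle: smooth each axis of the impulse independently
  gx <- bruteSmooth1D(replace(numeric(9), 5, 1), sigmaVox)
  gy <- bruteSmooth1D(replace(numeric(9), 5, 1), sigmaVox)
  gz <- bruteSmooth1D(replace(numeric(7), 4, 1), sigmaVox)
  expected <- outer(outer(gx, gy), gz)
  expect_equal(volumeData(sm)[, , , 1], expected, tolerance = 1e-6)
  expect_error(smoothGaussian(v, 0), "positive")
})

test_that("anisotropic voxels use per-axis sigma in voxel units", {
  arr <- array(0, c(11, 11, 5, 2)); arr[6, 6, 3, ] <- 1
  v <- VolumeSeries(arr, voxelMm = c(0.4, 0.8, 1.0))
  sm <- smoothGaussian(v, 1.0)
  sigMm <- 1.0 / (2 * sqrt(2 * log(2)))
  gx <- bruteSmooth1D(replace(numeric(11), 6, 1), sigMm / 0.4)
  gy <- bruteSmooth1D(replace(numeric(11), 6, 1), sigMm / 0.8)
  gz <- bruteSmooth1D(replace(numeric(5), 3, 1), sigMm / 1.0)
  expect_equal(volumeData(sm)[, , , 1], outer(outer(gx, gy), gz),
               tolerance = 1e-6)
})

test_that("confound regression matches a normal-equations oracle and is orthogonal", {
  set.seed(10)
  nT <- 120
  series <- matrix(rnorm(nT * 5), nT, 5)
  cf <- matrix(rnorm(nT * 3), nT, 3,
               dimnames = list(NULL, paste0("c", 1:3)))
  res <- regressConfounds(series, cf, detrend = TRUE)
  X <- cbind(1, seq_len(nT) - (nT + 1) / 2, cf)
  oracle <- series - X %*% solve(crossprod(X), crossprod(X, series))
  expect_equal(res, oracle, tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(X, res))), 1e-8 * max(abs(series)) * nT)
})

test_that("regressing a series on itself leaves ~zero; orthogonal confounds only demean/detrend", {
  set.seed(11)
  nT <- 100
  cf <- matrix(rnorm(nT), ncol = 1, dimnames = list(NULL, "c1"))
  res <- regressConfounds(cf, cf, detrend = FALSE)
  expect_lt(max(abs(res)), 1e-10)

  x <- matrix(rnorm(nT), ncol = 1)
  xc <- x - mean(x)
  # empirically decorrelate the confound from [1 | centered series]
  D <- cbind(1, xc)
  cfo <- cf - D %*% solve(crossprod(D), crossprod(D, cf))
  res2 <- regressConfounds(xc, cfo, detrend = FALSE)
  expect_equal(as.numeric(res2), as.numeric(xc), tolerance = 1e-8)
})

test_that("a rank-deficient confound design is rejected naming the collinear column", {
  nT <- 50
  cf <- data.frame(a = rnorm(nT))
  cf$b <- 2 * cf$a
  expect_error(regressConfounds(matrix(rnorm(nT)), cf), "b")
  # a constant confound is collinear with the intercept
  expect_error(regressConfounds(matrix(rnorm(nT)),
                                data.frame(const = rep(1, nT))), "const")
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones (FFT oracle)", {
  tr <- 1.5; nT <- 600
  tt <- (seq_len(nT) - 1) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  slow <- sin(2 * pi * 0.005 * tt)
  y <- bandpass(cbind(inband, slow), tr)
  expect_gte(fftAmplitude(y[, 1], 0.05, tr), 0.95 * fftAmplitude(inband, 0.05, tr))
  expect_lte(fftAmplitude(y[, 2], 0.005, tr), 0.10 * fftAmplitude(slow, 0.005, tr))
  # fast stopband (>= 2 * high)
  fast <- sin(2 * pi * 0.25 * tt)
  yf <- bandpass(cbind(fast), tr)
  expect_lte(fftAmplitude(yf[, 1], 0.25, tr), 0.10 * fftAmplitude(fast, 0.25, tr))
  # DC removed (relative to the input mean of 5; small filtfilt edge
  # transients keep this from being exactly zero)
  expect_lt(abs(mean(bandpass(cbind(rep(5, nT) + inband), tr)[, 1])) / 5, 1e-3)
})

test_that("band-pass of zero input is zero and is approximately idempotent", {
  tr <- 1.5; nT <- 600
  expect_true(all(bandpass(matrix(0, nT, 2), tr) == 0))
  tt <- (seq_len(nT) - 1) * tr
  x <- cbind(sin(2 * pi * 0.05 * tt) + 0.5 * sin(2 * pi * 0.03 * tt))
  once <- bandpass(x, tr)
  twice <- bandpass(once, tr)
  expect_lt(abs(fftAmplitude(twice[, 1], 0.05, tr) -
                fftAmplitude(once[, 1], 0.05, tr)),
            0.05 * fftAmplitude(once[, 1], 0.05, tr))
})

test_that("band edges above Nyquist are rejected with the computed Nyquist", {
  expect_error(bandpass(matrix(0, 10, 1), trSeconds = 1.5, highHz = 0.4),
               "0.333")
  expect_error(bandpass(matrix(0, 10, 1), trSeconds = 1.5,
                        lowHz = 0.2, highHz = 0.1), "lowHz")
})

test_that("ROI extraction equals brute-force voxel means and is exactly linear", {
  set.seed(20)
  arr <- array(rnorm(10 * 10 * 6 * 4), c(10, 10, 6, 4))
  v <- VolumeSeries(arr, voxelMm = 0.5)
  # cube of exactly 8 voxels: edge 1.0 mm = 2 voxels, center between voxels
  roi <- roiCube("oct", c(2.25, 2.25, 1.25), 1.0)
  got <- extractROITimeseries(v, roi)
  idx <- resolveROIVoxels(roi, c(10, 10, 6), 0.5)
  expect_identical(nrow(idx), 8L)
  oracle <- sapply(1:4, function(t) {
    acc <- 0
    for (r in seq_len(nrow(idx)))
      acc <- acc + arr[idx[r, 1] + 1, idx[r, 2] + 1, idx[r, 3] + 1, t]
    acc / nrow(idx)
  })
  expect_equal(got, oracle, tolerance = 1e-14)

  # linearity: extraction of a*v1 + b*v2 == a*s1 + b*s2 exactly
  arr2 <- array(rnorm(length(arr)), dim(arr))
  v2 <- VolumeSeries(arr2, voxelMm = 0.5)
  comb <- VolumeSeries(2 * arr - 3 * arr2, voxelMm = 0.5)
  expect_equal(extractROITimeseries(comb, roi),
               2 * got - 3 * extractROITimeseries(v2, roi),
               tolerance = 1e-12)

  # uniform volume -> constant series
  u <- VolumeSeries(array(4.2, c(6, 6, 4, 3)), voxelMm = 0.5)
  expect_equal(extractROITimeseries(u, roiCube("u", c(1.5, 1.5, 1), 1.2)),
               rep(4.2, 3), tolerance = 1e-14)

  # single-voxel geometry returns the voxel series exactly
  sv <- roiVoxel("one", c(3, 4, 2))
  expect_identical(extractROITimeseries(v, sv), arr[4, 5, 3, ])
})

test_that("a cube straddling the grid edge errors instead of clipping", {
  v <- VolumeSeries(array(0, c(6, 6, 4, 2)), voxelMm = 0.5)
  expect_error(extractROITimeseries(v, roiCube("edge", c(2.7, 1.5, 1), 1.0)),
               "edge")
  expect_error(resolveROIVoxels(roiVoxel("out", c(6, 0, 0)), c(6, 6, 4), 0.5),
               "out")
})
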