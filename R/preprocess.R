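## In-scope preprocessing tail for already-registered volumes. The pinned
## canonical order is: spatial smoothing -> confound regression -> temporal
## band-pass -> ROI extraction (extraction commutes with the temporal steps
## by linearity, so ROI-mode pipelines may extract first).

## 1D Gaussian smoothing operator with half-sample symmetric (reflective)
## boundary. Rows sum to 1 (constant images are invariant) and the folded
## matrix is symmetric for a symmetric kernel, so column sums are 1 too and
## total image mass is preserved.
gaussSmoothMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  radius <- max(1L, ceiling(4 * sigmaVox))
  offs <- (-radius):radius
  w <- exp(-offs^2 / (2 * sigmaVox^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i0 in 0:(n - 1)) {
    for (d in seq_along(offs)) {
      j0 <- i0 + offs[d]
      while (j0 < 0 || j0 >= n) {
        if (j0 < 0) j0 <- -1L - j0
        if (j0 >= n) j0 <- 2L * n - 1L - j0
      }
      S[i0 + 1, j0 + 1] <- S[i0 + 1, j0 + 1] + w[d]
    }
  }
  S
}

## Apply a matrix along one axis of a 4D array.
applyAlongAxis <- function(arr, S, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:4, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  m <- S %*% m
  out <- array(m, d[perm])
  aperm(out, order(perm))
}

#' Spatial Gaussian smoothing of a 4D series
#'
#' Convolves every volume with an isotropic (in mm) Gaussian kernel of the
#' given full width at half maximum: sigma = fwhm / (2 sqrt(2 ln 2)) per
#' axis, converted to voxel units using the volume's voxel size. Separable
#' implementation with reflective boundary handling; spatially constant
#' volumes are unchanged and total image mass is preserved.
#'
#' @param vol a [VolumeSeries-class].
#' @param fwhmMm full width at half maximum in mm (> 0).
#' @return A smoothed [VolumeSeries-class].
#' @export
smoothGaussian <- function(vol, fwhmMm) {
  if (!is.numeric(fwhmMm) || length(fwhmMm) != 1L || fwhmMm <= 0)
    stop("fwhmMm must be a positive scalar")
  sigmaMm <- fwhmMm / (2 * sqrt(2 * log(2)))
  arr <- vol@data
  for (axis in 1:3) {
    sigmaVox <- sigmaMm / vol@voxelMm[axis]
    S <- gaussSmoothMatrix(dim(arr)[axis], sigmaVox)
    arr <- applyAlongAxis(arr, S, axis)
  }
  new("VolumeSeries", data = arr, voxelMm = vol@voxelMm,
      trSeconds = vol@trSeconds, spaceLabel = vol@spaceLabel,
      brainMask = vol@brainMask)
}

#' Nuisance regression of confounds
#'
#' Ordinary-least-squares residuals of every series column on an intercept
#' plus the confound regressors (optionally plus a linear trend, on by
#' default: detrending is standard for resting-state series). Residuals are
#' orthogonal to every regressor. A rank-deficient design is rejected with
#' the collinear columns named.
#'
#' @param series T x N numeric matrix of time series (one column per voxel
#'   or ROI).
#' @param confounds T x K matrix or data frame of regressors (may be `NULL`
#'   for detrend/demean only).
#' @param detrend add a linear trend regressor (default `TRUE`).
#' @return T x N residual matrix (column names preserved).
#' @export
#' @examples
#' tt <- 1:100
#' x <- cbind(a = sin(tt / 5) + 0.1 * tt, b = rnorm(100))
#' r <- regressConfounds(x, data.frame(drift = tt / 100))
#' max(abs(crossprod(r[, 1], tt / 100)))  # orthogonal to the regressor
regressConfounds <- function(series, confounds = NULL, detrend = TRUE) {
  series <- as.matrix(series)
  nT <- nrow(series)
  X <- matrix(1, nT, 1, dimnames = list(NULL, "intercept"))
  if (detrend)
    X <- cbind(X, trend = seq_len(nT) - (nT + 1) / 2)
  if (!is.null(confounds)) {
    cf <- as.matrix(confounds)
    if (nrow(cf) != nT)
      stop(sprintf("confounds have %d rows but series has %d time points",
                   nrow(cf), nT))
    if (any(!is.finite(cf)))
      stop("confounds contain non-finite entries")
    if (is.null(colnames(cf)))
      colnames(cf) <- paste0("confound_", seq_len(ncol(cf)))
    X <- cbind(X, cf)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("confound design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qrX, series)
  dimnames(res) <- dimnames(series)
  res
}

#' Temporal band-pass filtering
#'
#' Zero-phase (forward-backward) Butterworth filtering of every column,
#' order 4 per pass, passing `lowHz`-`highHz` (defaults 0.01-0.1 Hz). The
#' column mean (DC) is removed first. `lowHz = 0` degenerates to a low-pass.
#'
#' @param series T x N numeric matrix.
#' @param trSeconds repetition time in seconds (sampling period).
#' @param lowHz,highHz band edges in Hz; requires
#'   `0 <= lowHz < highHz < 1 / (2 trSeconds)`.
#' @return Filtered T x N matrix.
#' @export
bandpass <- function(series, trSeconds, lowHz = 0.01, highHz = 0.1) {
  series <- as.matrix(series)
  nyquist <- 1 / (2 * trSeconds)
  if (lowHz < 0 || lowHz >= highHz)
    stop("need 0 <= lowHz < highHz")
  if (highHz >= nyquist)
    stop(sprintf("highHz (%.4g Hz) must be below the Nyquist frequency %.4g Hz at TR %.3g s",
                 highHz, nyquist, trSeconds))
  centered <- sweep(series, 2, colMeans(series))
  filt <- if (lowHz > 0) {
    butter(4, c(lowHz, highHz) / nyquist, type = "pass")
  } else {
    butter(4, highHz / nyquist, type = "low")
  }
  out <- apply(centered, 2, function(col) filtfilt(filt, col))
  out <- matrix(out, nrow = nrow(series))
  dimnames(out) <- dimnames(series)
  out
}

#' Extract the mean ROI time course
#'
#' Unweighted mean across the ROI's member voxels at each time point;
#' single-voxel geometry returns that voxel's series exactly. An ROI
#' outside the grid, straddling its boundary, or resolving to zero voxels
#' is an error (never silently clipped).
#'
#' @param vol a [VolumeSeries-class].
#' @param roi one-row ROI data frame ([roiCube()] / [roiVoxel()]).
#' @return Numeric vector of length T.
#' @export
extractROITimeseries <- function(vol, roi) {
  d <- dim(vol@data)
  vox <- resolveROIVoxels(roi, d[1:3], vol@voxelMm)
  lin <- roiLinearIndex(vox, d[1:3])
  flat <- matrix(vol@data, prod(d[1:3]), d[4])
  if (length(lin) == 1L) return(flat[lin, ])
  colMeans(flat[lin, , drop = FALSE])
}

#' Extract all ROI time courses as a matrix
#'
#' @param vol a [VolumeSeries-class].
#' @param rois ROI data frame (one row per region).
#' @return T x nROI matrix, columns named by ROI label.
#' @export
extractAllROITimeseries <- function(vol, rois) {
  d <- dim(vol@data)
  flat <- matrix(vol@data, prod(d[1:3]), d[4])
  out <- vapply(seq_len(nrow(rois)), function(r) {
    vox <- resolveROIVoxels(rois[r, ], d[1:3], vol@voxelMm)
    lin <- roiLinearIndex(vox, d[1:3])
    if (length(lin) == 1L) flat[lin, ]
    else colMeans(flat[lin, , drop = FALSE])
  }, numeric(d[4]))
  colnames(out) <- rois$label
  out
}
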