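#' Pearson correlation of two time series
#'
#' Standard product-moment correlation with explicit precondition checks: at
#' least 3 time points and nonzero variance in both series (a constant
#' series has no direction of covariation, so the error names the offender
#' rather than returning `NA`).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in [-1, 1].
#' @export
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 2, 3, 5))
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("series have different lengths")
  if (length(x) < 3L)
    stop("need at least 3 time points for a correlation")
  if (sd(x) == 0) stop("first series (x) is constant; correlation undefined")
  if (sd(y) == 0) stop("second series (y) is constant; correlation undefined")
  cor(x, y)
}

#' Fisher r-to-z transform
#'
#' `atanh(r)`, variance-stabilizing the correlation for averaging across
#' scans. Values with `|r| >= 1 - 1e-7` are clamped to the boundary with a
#' warning so the transform stays finite.
#'
#' @param r numeric vector of correlations.
#' @return `atanh` of the (possibly clamped) input.
#' @export
#' @examples
#' fisherZ(0.5) - 0.5 * log(1.5 / 0.5)  # log identity
fisherZ <- function(r) {
  eps <- 1e-7
  nClamp <- sum(abs(r) > 1 - eps, na.rm = TRUE)
  if (nClamp > 0) {
    warning(sprintf("%d correlation(s) clamped to +/-(1 - 1e-7) before atanh",
                    nClamp))
    r <- pmin(pmax(r, -(1 - eps)), 1 - eps)
  }
  atanh(r)
}

#' Seed-based functional connectivity
#'
#' Fisher-z of the Pearson correlation between a seed's mean time course and
#' each target. Two modes:
#' * ROI mode (`scan` is a T x nROI matrix): targets are the other columns
#'   (or `targetLabels`); returns a named-vector `FCMap`.
#' * map mode (`scan` is a [VolumeSeries-class], `seedROI` given): the seed
#'   course is extracted with [extractROITimeseries()] and correlated with
#'   every in-mask voxel; returns a 3D-array `FCMap` with masked-out voxels
#'   `NA` (absent, not zero).
#'
#' Constant target series get `NA` with a single warning reporting the
#' count. Seed FC is invariant to any common positive affine rescaling of
#' the input series.
#'
#' @param scan T x nROI matrix with named columns, or a
#'   [VolumeSeries-class] (already preprocessed).
#' @param seedLabel seed column name (ROI mode).
#' @param seedROI one-row ROI data frame (map mode).
#' @param targetLabels target columns (ROI mode; default: the canonical
#'   targets present in the matrix).
#' @param speciesLabel species label recorded in the result.
#' @return A scan-level [FCMap-class].
#' @export
seedFC <- function(scan, seedLabel = NULL, seedROI = NULL,
                   targetLabels = NULL, speciesLabel = "unspecified") {
  if (is(scan, "VolumeSeries")) {
    stopifnot(!is.null(seedROI))
    seedSeries <- extractROITimeseries(scan, seedROI)
    d <- dim(scan@data)
    flat <- matrix(scan@data, prod(d[1:3]), d[4])
    inMask <- if (is.null(scan@brainMask)) rep(TRUE, prod(d[1:3]))
              else as.logical(scan@brainMask)
    sds <- apply(flat, 1, sd)
    usable <- inMask & sds > 0
    z <- rep(NA_real_, prod(d[1:3]))
    if (any(usable)) {
      r <- as.numeric(cor(seedSeries, t(flat[usable, , drop = FALSE])))
      z[usable] <- fisherZ(r)
    }
    nConst <- sum(inMask & sds == 0)
    if (nConst > 0)
      warning(sprintf("%d in-mask voxel(s) had constant series; set to NA",
                      nConst))
    return(new("FCMap", values = array(z, d[1:3]),
               seedLabel = seedROI$label, speciesLabel = speciesLabel,
               level = "scan", nScans = 1L))
  }
  series <- as.matrix(scan)
  stopifnot(!is.null(seedLabel), seedLabel %in% colnames(series))
  if (is.null(targetLabels))
    targetLabels <- intersect(colnames(series), canonicalTargets())
  if (!all(targetLabels %in% colnames(series)))
    stop("targets missing from series: ",
         paste(setdiff(targetLabels, colnames(series)), collapse = ", "))
  seedSeries <- series[, seedLabel]
  if (sd(seedSeries) == 0)
    stop(sprintf("seed '%s' has a constant time course", seedLabel))
  rvec <- vapply(targetLabels, function(tgt) {
    y <- series[, tgt]
    if (sd(y) == 0) NA_real_ else cor(seedSeries, y)
  }, numeric(1))
  vals <- rvec
  ok <- !is.na(rvec)
  vals[ok] <- fisherZ(rvec[ok])  # warns once if any |r| clamps
  nConst <- sum(!ok)
  if (nConst > 0)
    warning(sprintf("%d constant target series for seed '%s'; set to NA",
                    nConst, seedLabel))
  new("FCMap", values = vals, seedLabel = seedLabel,
      speciesLabel = speciesLabel, level = "scan", nScans = 1L)
}

#' Group-level functional connectivity
#'
#' Elementwise unweighted mean of Fisher-z values across scan-level maps
#' (scan-level fixed effects: all runs of all animals pooled with equal
#' weight). All maps must share seed, species, and shape.
#'
#' @param scanMaps list of scan-level [FCMap-class] objects.
#' @return A group-level [FCMap-class] with `nScans` set.
#' @export
groupFC <- function(scanMaps) {
  stopifnot(length(scanMaps) >= 1L)
  ref <- scanMaps[[1]]
  for (m in scanMaps) {
    if (!identical(m@seedLabel, ref@seedLabel) ||
        !identical(m@speciesLabel, ref@speciesLabel))
      stop("cannot aggregate maps with mixed seeds or species")
    if (!identical(dim(m@values), dim(ref@values)) ||
        !identical(names(m@values), names(ref@values)))
      stop("cannot aggregate maps with mismatched grids/targets")
  }
  acc <- ref@values
  if (length(scanMaps) > 1L)
    for (m in scanMaps[-1]) acc <- acc + m@values
  acc <- acc / length(scanMaps)
  new("FCMap", values = acc, seedLabel = ref@seedLabel,
      speciesLabel = ref@speciesLabel, level = "group",
      nScans = length(scanMaps))
}
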