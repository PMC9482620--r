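## ROI specifications are plain data frames (the on-disk sidecar format),
## one row per region, with columns:
##   label, role ("seed"/"target"), space, geometry ("cube"/"voxel"),
##   center_x_mm, center_y_mm, center_z_mm, edge_mm   (cube geometry)
##   ix, iy, iz                                       (0-based voxel indices)
## mm coordinates follow the volume's affine convention: the center of the
## voxel with 0-based index (i, j, k) lies at (i, j, k) * voxelMm.

roiColumns <- c("label", "role", "space", "geometry",
                "center_x_mm", "center_y_mm", "center_z_mm", "edge_mm",
                "ix", "iy", "iz")

#' Define a cubic ROI
#'
#' A seed or target region as an axis-aligned cube: center in mm plus edge
#' length in mm. A voxel belongs to the cube iff its center lies within the
#' closed cube.
#'
#' @param label region name.
#' @param centerMm numeric(3), cube center in mm.
#' @param edgeMm positive edge length in mm.
#' @param role `"seed"` or `"target"`.
#' @param space species-space label.
#' @return One-row ROI data frame.
#' @seealso [roiVoxel()], [resolveROIVoxels()]
#' @export
#' @examples
#' roiCube("M1", c(2, 2, 1.5), edgeMm = 1.5)
roiCube <- function(label, centerMm, edgeMm, role = "target",
                    space = "unspecified") {
  stopifnot(length(centerMm) == 3L, edgeMm > 0,
            role %in% c("seed", "target"))
  data.frame(label = label, role = role, space = space, geometry = "cube",
             center_x_mm = centerMm[1], center_y_mm = centerMm[2],
             center_z_mm = centerMm[3], edge_mm = edgeMm,
             ix = NA_integer_, iy = NA_integer_, iz = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Define a single-voxel ROI
#'
#' @param label region name.
#' @param index integer(3), 0-based voxel index.
#' @param role `"seed"` or `"target"`.
#' @param space species-space label.
#' @return One-row ROI data frame.
#' @export
roiVoxel <- function(label, index, role = "seed", space = "unspecified") {
  stopifnot(length(index) == 3L, role %in% c("seed", "target"))
  data.frame(label = label, role = role, space = space, geometry = "voxel",
             center_x_mm = NA_real_, center_y_mm = NA_real_,
             center_z_mm = NA_real_, edge_mm = NA_real_,
             ix = as.integer(index[1]), iy = as.integer(index[2]),
             iz = as.integer(index[3]), stringsAsFactors = FALSE)
}

roiCenterMm <- function(roi, voxelMm) {
  if (roi$geometry == "cube") {
    c(roi$center_x_mm, roi$center_y_mm, roi$center_z_mm)
  } else {
    c(roi$ix, roi$iy, roi$iz) * voxelMm
  }
}

## Is the ROI fully inside the grid's bounding box?  The grid of n voxels of
## size v spans [-v/2, (n - 1/2) * v] per axis (voxel centers at 0 .. (n-1)v).
roiInsideGrid <- function(roi, gridShape, voxelMm) {
  if (roi$geometry == "voxel") {
    idx <- c(roi$ix, roi$iy, roi$iz)
    return(all(idx >= 0L) && all(idx <= gridShape - 1L))
  }
  ctr <- c(roi$center_x_mm, roi$center_y_mm, roi$center_z_mm)
  half <- roi$edge_mm / 2
  lo <- ctr - half
  hi <- ctr + half
  all(lo >= -voxelMm / 2) && all(hi <= (gridShape - 0.5) * voxelMm)
}

#' Resolve an ROI to its member voxels
#'
#' Converts one ROI row to the 0-based indices of its member voxels on a
#' grid. Cube membership is voxel-center-in-closed-cube. A cube that
#' straddles the grid boundary is an error, never silently clipped.
#'
#' @param roi one-row ROI data frame ([roiCube()] / [roiVoxel()]).
#' @param gridShape integer(3) grid dimensions.
#' @param voxelMm voxel size in mm (scalar or length 3).
#' @return Integer matrix, one row per member voxel, columns i, j, k
#'   (0-based).
#' @export
resolveROIVoxels <- function(roi, gridShape, voxelMm) {
  if (length(voxelMm) == 1L) voxelMm <- rep(voxelMm, 3L)
  gridShape <- as.integer(gridShape)
  if (!roiInsideGrid(roi, gridShape, voxelMm))
    stop(sprintf("ROI '%s' extends outside the %s grid; refusing to clip",
                 roi$label, paste(gridShape, collapse = "x")))
  if (roi$geometry == "voxel") {
    return(matrix(as.integer(c(roi$ix, roi$iy, roi$iz)), nrow = 1,
                  dimnames = list(NULL, c("i", "j", "k"))))
  }
  ctr <- c(roi$center_x_mm, roi$center_y_mm, roi$center_z_mm)
  half <- roi$edge_mm / 2
  ranges <- lapply(1:3, function(a) {
    lo <- ceiling((ctr[a] - half[1]) / voxelMm[a] - 1e-9)
    hi <- floor((ctr[a] + half[1]) / voxelMm[a] + 1e-9)
    seq.int(max(lo, 0L), min(hi, gridShape[a] - 1L))
  })
  if (any(lengths(ranges) == 0L))
    stop(sprintf("ROI '%s' resolves to 0 voxels at %.3g mm resolution",
                 roi$label, voxelMm[1]))
  g <- expand.grid(i = ranges[[1]], j = ranges[[2]], k = ranges[[3]])
  as.matrix(g)
}

## Linear (1-based) indices into a flattened X*Y*Z spatial grid.
roiLinearIndex <- function(vox, gridShape) {
  1L + vox[, 1] + gridShape[1] * (vox[, 2] + gridShape[2] * vox[, 3])
}

#' Read / write an ROI sidecar table
#'
#' TSV with columns label, role, space, geometry, center_x_mm, center_y_mm,
#' center_z_mm, edge_mm, ix, iy, iz.
#'
#' @param path file path.
#' @return `readROITable` returns the ROI data frame.
#' @export
readROITable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(roiColumns, names(df))
  if (length(missing))
    stop("ROI table is missing columns: ", paste(missing, collapse = ", "))
  df[, roiColumns]
}

#' @rdname readROITable
#' @param rois ROI data frame.
#' @export
writeROITable <- function(rois, path) {
  write.table(rois[, roiColumns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
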