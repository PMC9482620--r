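## Floating-point outputs are written with 6 significant digits so that
## manifests can hash a canonical, platform-stable text form.
formatReal <- function(x) {
  if (is.matrix(x)) {
    out <- apply(x, 2, function(col) sprintf("%.6g", col))
    colnames(out) <- colnames(x)
    return(out)
  }
  sprintf("%.6g", x)
}

#' Write a VolumeSeries as NIfTI-1
#'
#' Voxel size goes to `pixdim[1:3]` (mm) and the repetition time to
#' `pixdim[4]` (seconds).
#'
#' @param vol a [VolumeSeries-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolumeSeries <- function(vol, path) {
  img <- asNifti(vol@data)
  pixdim(img) <- c(vol@voxelMm, vol@trSeconds)
  pixunits(img) <- c("mm", "s")
  writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a VolumeSeries
#'
#' @param path input path.
#' @param spaceLabel species-space label to attach.
#' @param brainMask optional 3D mask.
#' @return A [VolumeSeries-class].
#' @export
readVolumeSeries <- function(path, spaceLabel = "unspecified",
                             brainMask = NULL) {
  img <- readNifti(path)
  pd <- pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI volume, got ", length(dim(arr)), "D: ", path)
  VolumeSeries(arr, voxelMm = pd[1:3],
               trSeconds = if (length(pd) >= 4) pd[4] else 1,
               spaceLabel = spaceLabel, brainMask = brainMask)
}

#' Read / write confound regressor tables
#'
#' TSV with a header row, one column per regressor, T rows.
#'
#' @param path file path.
#' @return `readConfounds` returns a data frame.
#' @export
readConfounds <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (any(!vapply(df, is.numeric, logical(1))))
    stop("confound table has non-numeric columns: ", path)
  if (any(!is.finite(as.matrix(df))))
    stop("confound table contains non-finite entries: ", path)
  df
}

#' @rdname readConfounds
#' @param confounds data frame or matrix of regressors.
#' @export
writeConfounds <- function(confounds, path) {
  write.table(formatReal(as.matrix(confounds)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an FCMap
#'
#' ROI mode writes a TSV (`target`, `z`); map mode writes a 3D NIfTI-1
#' volume of Fisher-z values (masked voxels as `NA`).
#'
#' @param fc an [FCMap-class].
#' @param path output path (`.tsv`, `.nii` or `.nii.gz`).
#' @param voxelMm voxel size for map mode.
#' @return The path, invisibly.
#' @export
writeFCMap <- function(fc, path, voxelMm = c(0.5, 0.5, 0.5)) {
  v <- fc@values
  if (is.null(dim(v))) {
    df <- data.frame(target = names(v), z = formatReal(as.numeric(v)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    img <- asNifti(v)
    pixdim(img) <- voxelMm
    pixunits(img) <- c("mm", "s")
    writeNifti(img, path)
  }
  invisible(path)
}

#' Write fingerprints as a wide TSV
#'
#' One row per fingerprint: `species`, `seed`, `level`, `normalized`, then
#' the 8 canonical target columns. The canonical target order is stored
#' explicitly in the header so files are self-describing.
#'
#' @param fps list of [Fingerprint-class] objects.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeFingerprints <- function(fps, path) {
  rows <- lapply(fps, function(f) {
    data.frame(species = f@speciesLabel, seed = f@seedLabel,
               level = f@level, normalized = f@normalized,
               t(vapply(f@values, identity, numeric(1))),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  for (tgt in canonicalTargets()) df[[tgt]] <- formatReal(df[[tgt]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Long-format fingerprint table for spider/radar plots
#'
#' @param fps list of [Fingerprint-class] objects.
#' @return Data frame with columns `species`, `seed`, `level`, `target`,
#'   `value`, target levels in canonical order.
#' @export
fingerprintLongTable <- function(fps) {
  do.call(rbind, lapply(fps, function(f) {
    data.frame(species = f@speciesLabel, seed = f@seedLabel, level = f@level,
               target = factor(canonicalTargets(),
                               levels = canonicalTargets()),
               value = as.numeric(f@values), stringsAsFactors = FALSE)
  }))
}
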