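#' Read and validate a study configuration
#'
#' YAML or JSON (decided by extension). Top-level fields:
#' * `seed`: integer base RNG seed (per-stage seeds derive from it by a
#'   fixed counter scheme);
#' * `output_dir`: where the output bundle goes;
#' * `preprocessing`: `fwhm_mm` (optional; omit to skip smoothing),
#'   `low_hz` (default 0.01), `high_hz` (default 0.1), `detrend`
#'   (default `TRUE`);
#' * `fingerprint`: `target_order` -- exactly 8 labels, must equal the
#'   canonical order;
#' * `permutation`: `enabled` (default `TRUE`), `n_iterations`
#'   (default 10000);
#' * `report`: `similarity_threshold` (default 0.75);
#' * `species`: list of blocks with `label`, optional `roi_file` (sidecar
#'   TSV; required for volume scans), `seeds` (labels), and `scans`, each
#'   scan with either `roi_table` (TSV of ROI series) or `volume`
#'   (NIfTI-1) plus optional `confounds` (TSV).
#'
#' Referenced paths are checked at validation time; species labels must be
#' unique.
#'
#' @param path config file path.
#' @return Validated config list (class `"crossFCConfig"`).
#' @export
readStudyConfig <- function(path) {
  ext <- tolower(file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) read_yaml(path)
         else if (ext == "json") read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON: ", path)
  validateStudyConfig(cfg, dir = dirname(path))
}

validateStudyConfig <- function(cfg, dir = ".") {
  defaults <- list(
    seed = 1L,
    preprocessing = list(low_hz = 0.01, high_hz = 0.1, detrend = TRUE),
    fingerprint = list(target_order = as.list(canonicalTargets())),
    permutation = list(enabled = TRUE, n_iterations = 10000L),
    report = list(similarity_threshold = 0.75)
  )
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]])) cfg[[k]] <- modifyList(defaults[[k]], cfg[[k]])
  }
  tord <- unlist(cfg$fingerprint$target_order)
  if (length(tord) != 8L)
    stop("fingerprint target_order must have exactly 8 labels")
  if (!identical(tord, canonicalTargets()))
    stop("target_order must be the canonical order: ",
         paste(canonicalTargets(), collapse = ", "))
  if (is.null(cfg$species) || !length(cfg$species))
    stop("config needs at least one species block")
  labels <- vapply(cfg$species, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("species labels must be unique")
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  for (si in seq_along(cfg$species)) {
    sp <- cfg$species[[si]]
    if (!is.null(sp$roi_file)) {
      sp$roi_file <- resolve(sp$roi_file)
      if (!file.exists(sp$roi_file))
        stop("missing roi_file for species ", sp$label, ": ", sp$roi_file)
    }
    if (is.null(sp$scans) || !length(sp$scans))
      stop("species ", sp$label, " has no scans")
    for (ci in seq_along(sp$scans)) {
      sc <- sp$scans[[ci]]
      for (f in intersect(names(sc), c("roi_table", "volume", "confounds"))) {
        sc[[f]] <- resolve(sc[[f]])
        if (!file.exists(sc[[f]]))
          stop("missing ", f, " for species ", sp$label, ": ", sc[[f]])
      }
      if (is.null(sc$roi_table) && is.null(sc$volume))
        stop("each scan needs either roi_table or volume (species ",
             sp$label, ")")
      if (!is.null(sc$volume) && is.null(sp$roi_file))
        stop("volume-mode species ", sp$label, " needs roi_file")
      sp$scans[[ci]] <- sc
    }
    cfg$species[[si]] <- sp
  }
  if (is.null(cfg$output_dir)) cfg$output_dir <- "crossFC_out"
  class(cfg) <- c("crossFCConfig", "list")
  cfg
}

## Per-species stage: load scans, preprocess, compute scan fingerprints per
## seed, group-average, normalize.
processSpecies <- function(sp, pp) {
  rois <- if (!is.null(sp$roi_file)) readROITable(sp$roi_file) else NULL
  scanSeries <- lapply(sp$scans, function(sc) {
    if (!is.null(sc$roi_table)) {
      series <- readROISeries(sc$roi_table)
      tr <- if (!is.null(sc$tr_seconds)) sc$tr_seconds else 1.5
    } else {
      vol <- readVolumeSeries(sc$volume, spaceLabel = sp$label)
      if (!is.null(pp$fwhm_mm)) vol <- smoothGaussian(vol, pp$fwhm_mm)
      series <- extractAllROITimeseries(vol, rois)
      tr <- vol@trSeconds
    }
    cf <- if (!is.null(sc$confounds)) readConfounds(sc$confounds) else NULL
    series <- regressConfounds(series, cf, detrend = isTRUE(pp$detrend))
    series <- bandpass(series, tr, pp$low_hz, pp$high_hz)
    series
  })
  seeds <- unlist(sp$seeds)
  if (is.null(seeds)) {
    seeds <- if (!is.null(rois)) rois$label[rois$role == "seed"]
             else setdiff(colnames(scanSeries[[1]]), canonicalTargets())
  }
  perSeed <- lapply(seeds, function(seed) {
    maps <- lapply(scanSeries, function(series)
      seedFC(series, seedLabel = seed, speciesLabel = sp$label))
    scanFps <- do.call(rbind, lapply(maps, function(m)
      extractFingerprint(m)@values))
    groupRaw <- extractFingerprint(groupFC(maps))
    list(seed = seed, scanFps = scanFps, groupRaw = groupRaw,
         groupNorm = normalizeFingerprint(groupRaw))
  })
  names(perSeed) <- seeds
  perSeed
}

#' Run the full fingerprinting pipeline
#'
#' Orchestrates every stage for all species in a config: preprocessing
#' (smoothing for volume scans, confound regression, band-pass), seed FC,
#' scan- and group-level fingerprints, normalization, pairwise
#' cosine-similarity matrices with permutation tests, and threshold-count
#' reports. Writes the output bundle (fingerprint TSVs, similarity
#' TSV/JSON per species pair, permutation JSONs, a run log recording every
#' pinned analysis decision, and a manifest of md5 content hashes).
#' Rerunning with an identical config and seed reproduces identical
#' manifests.
#'
#' @param config a config list from [readStudyConfig()] /
#'   [validateStudyConfig()], or a path to a config file.
#' @param outputDir overrides the config's `output_dir`.
#' @return Invisibly, a list: `fingerprints` (list of
#'   [Fingerprint-class]), `scanFingerprints` (per species, per seed
#'   matrices), `similarity` (list of [SimilarityMatrix-class] per pair),
#'   `counts` (per-pair threshold counts), `manifest` (data frame),
#'   `outputDir`.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readStudyConfig(config)
  if (!inherits(config, "crossFCConfig"))
    config <- validateStudyConfig(config)
  outDir <- if (!is.null(outputDir)) outputDir else config$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pp <- config$preprocessing

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  species <- lapply(config$species, function(sp)
    stage(paste0("fingerprints:", sp$label), processSpecies(sp, pp)))
  names(species) <- vapply(config$species, function(s) s$label, character(1))

  files <- character()
  ## fingerprint tables (raw + normalized, group level) per species
  allFps <- list()
  for (lab in names(species)) {
    fps <- unlist(lapply(species[[lab]], function(x)
      list(x$groupRaw, x$groupNorm)))
    allFps <- c(allFps, fps)
    f <- file.path(outDir, paste0("fingerprints_", lab, ".tsv"))
    writeFingerprints(fps, f)
    files <- c(files, f)
    f <- file.path(outDir, paste0("fingerprints_", lab, "_long.tsv"))
    write.table(fingerprintLongTable(fps), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }

  ## pairwise similarity + permutation
  sims <- list(); counts <- list()
  labs <- names(species)
  pairIdx <- 0L
  if (length(labs) >= 2L) {
    for (i in seq_len(length(labs) - 1L)) {
      for (j in seq((i + 1L), length(labs))) {
        pairIdx <- pairIdx + 1L
        a <- species[[labs[i]]]; b <- species[[labs[j]]]
        key <- paste(labs[i], labs[j], sep = "_vs_")
        sim <- stage(paste0("similarity:", key), buildSimilarityMatrix(
          lapply(a, `[[`, "groupNorm"), lapply(b, `[[`, "groupNorm"),
          scansA = if (isTRUE(config$permutation$enabled))
            lapply(a, `[[`, "scanFps"),
          scansB = if (isTRUE(config$permutation$enabled))
            lapply(b, `[[`, "scanFps"),
          nIterations = config$permutation$n_iterations,
          rngSeed = deriveSeed(config$seed, 1000L + pairIdx)))
        sims[[key]] <- sim
        counts[[key]] <- reportThresholdCounts(
          sim, config$report$similarity_threshold)
        f <- file.path(outDir, paste0("similarity_", key, ".tsv"))
        writeSimilarityTSV(sim, f); files <- c(files, f)
        f <- file.path(outDir, paste0("similarity_", key, ".json"))
        writeSimilarityJSON(sim, counts[[key]],
                            config$report$similarity_threshold, f)
        files <- c(files, f)
      }
    }
  }

  ## run log: every pinned analysis decision, verbatim, for provenance
  logFile <- file.path(outDir, "run_log.txt")
  writeLines(c(
    "crossFC run log",
    sprintf("base RNG seed: %d (per-stage seeds: (seed + 10007*k) mod 2^31-1)",
            config$seed),
    sprintf("species: %s", paste(labs, collapse = ", ")),
    sprintf("smoothing: %s",
            if (is.null(pp$fwhm_mm)) "none (ROI mode or pre-smoothed)"
            else sprintf("isotropic Gaussian, FWHM %g mm, reflective boundary",
                         pp$fwhm_mm)),
    "confound regression: OLS on [intercept | linear trend (if detrend) | confounds]",
    sprintf("detrend: %s", isTRUE(pp$detrend)),
    sprintf("band-pass: Butterworth order 4 per pass, zero-phase forward-backward, %g-%g Hz",
            pp$low_hz, pp$high_hz),
    "correlation: Pearson; z transform: Fisher atanh, clamp at |r| = 1 - 1e-7",
    "aggregation: scan-level fixed effects (all runs pooled, equal weight)",
    "fingerprint: group-average raw z, then min-max normalization",
    sprintf("canonical target order: %s",
            paste(canonicalTargets(), collapse = ", ")),
    sprintf("permutation: %s, %d iterations per cell, pooled shuffle preserving group sizes",
            if (isTRUE(config$permutation$enabled)) "enabled" else "disabled",
            as.integer(config$permutation$n_iterations)),
    "percentile: lower empirical order statistic at index ceiling(q/100*n), q = 1",
    "decision: one-sided, strict (observed < 1st percentile => different)",
    sprintf("similarity report threshold: %g (ties count as above)",
            config$report$similarity_threshold)
  ), logFile)
  files <- c(files, logFile)

  ## manifest: md5 of the canonical text form of every output
  manifest <- data.frame(file = basename(files),
                         md5 = unname(md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(fingerprints = allFps,
                 scanFingerprints = lapply(species, function(sp)
                   lapply(sp, `[[`, "scanFps")),
                 similarity = sims, counts = counts, manifest = manifest,
                 outputDir = outDir))
}

#' Count similarity-matrix cells relative to a threshold
#'
#' Reproduces the report framing "N of M comparisons below threshold":
#' cells strictly below, cells at-or-above (ties count as above), and the
#' number of significantly different cells if permutation results are
#' attached.
#'
#' @param sim a [SimilarityMatrix-class].
#' @param threshold report threshold (default 0.75).
#' @return List: `below`, `above`, `significant` (`NA` if no tests),
#'   `nCells`, `threshold`.
#' @export
reportThresholdCounts <- function(sim, threshold = 0.75) {
  v <- sim@cosine
  list(below = sum(v < threshold), above = sum(v >= threshold),
       significant = if (all(is.na(sim@significant))) NA_integer_
                     else sum(sim@significant, na.rm = TRUE),
       nCells = length(v), threshold = threshold)
}

writeSimilarityTSV <- function(sim, path) {
  m <- sim@cosine
  df <- data.frame(seed_A = rownames(m)[row(m)],
                   seed_B = colnames(m)[col(m)],
                   cosine = formatReal(as.numeric(m)),
                   significant = as.logical(sim@significant),
                   stringsAsFactors = FALSE)
  df <- df[order(df$seed_A, df$seed_B), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

writeSimilarityJSON <- function(sim, counts, threshold, path) {
  cells <- list()
  m <- sim@cosine
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    key <- paste(rownames(m)[i], colnames(m)[j], sep = "|")
    pr <- sim@permResults[[key]]
    cells[[key]] <- list(
      seed_A = rownames(m)[i], seed_B = colnames(m)[j],
      cosine = as.numeric(formatReal(m[i, j])),
      significant = if (is.na(sim@significant[i, j])) NULL
                    else sim@significant[i, j],
      threshold_1pct = if (is.null(pr)) NULL
                       else as.numeric(formatReal(pr@threshold)),
      empirical_p = if (is.null(pr)) NULL
                    else as.numeric(formatReal(pr@empiricalP)),
      n_iterations = if (is.null(pr)) NULL else pr@nIterations,
      rng_seed = if (is.null(pr)) NULL else pr@rngSeed,
      group_sizes = if (is.null(pr)) NULL else pr@groupSizes)
  }
  out <- list(species_A = sim@speciesA, species_B = sim@speciesB,
              n_cells = length(m), report_threshold = threshold,
              counts = counts, cells = cells)
  write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
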