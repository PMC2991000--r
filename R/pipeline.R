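# Pipeline orchestration: the four-stage segmentation run and the phantom
# validation study, with file outputs for command-line use.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full four-stage effusion quantification
#'
#' Stage 1 segments femur and tibia in T1 and transports them to the T2
#' frame; stage 2 masks bones, patella and fat into the masked images set;
#' stage 3 segments fluid candidates by recursive thresholding and filters
#' them by anatomic position relative to the bones; stage 4 meshes the final
#' effusion object and computes its subvoxel volume.
#'
#' @param t1,t2 \linkS4class{ImageVolume}s or file paths (NIfTI or DICOM
#'   directory).
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir optional output directory; when given, the effusion mask
#'   (NIfTI), volume result (JSON), candidate audit table (CSV), stage log
#'   and resolved config (YAML) are written there.
#' @return List with \code{effusion} (mask), \code{volume}
#'   (\linkS4class{VolumeResult}), \code{bones}, \code{candidates} audit
#'   data frame, \code{thresholds} per stage, and \code{config}.
#' @export
runSegment <- function(t1, t2, config = effusionConfig(), outDir = NULL) {
  if (is.character(t1))
    t1 <- .stage("stage 1: bone segmentation (T1 input)", loadVolume(t1, "T1"))
  if (is.character(t2)) t2 <- .stage("stage 2: T2 input", loadVolume(t2, "T2"))
  if (!is(t1, "ImageVolume"))
    stop("[stage 1: bone segmentation (T1 input)] missing T1 volume")
  bones <- .stage("stage 1: bone segmentation", segmentBones(t1, t2, config))
  mset <- .stage("stage 2: masking", buildMaskedSet(t2, bones, config))
  cands <- .stage("stage 3: fluid segmentation",
                  segmentFluidCandidates(mset, config))
  pouch <- pouchRegion(bones, config@pouchMarginMm)
  retained <- .stage("stage 3: anatomic filtering",
                     anatomicFilter(cands, bones, pouch, config))
  effusion <- .stage("stage 3: repair", finalizeEffusion(retained, mset, config))
  volume <- .stage("stage 4: volume calculation", meshAndVolume(effusion, config))
  thresholds <- list(bone = attr(bones, "thresholds"),
                     fluid = as.numeric(attr(cands, "threshold")),
                     fluidPass1 = attr(attr(cands, "threshold"), "t1"))
  out <- list(effusion = effusion, volume = volume, bones = bones,
              candidates = attr(retained, "audit"), thresholds = thresholds,
              config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMask(effusion, file.path(outDir, "effusion_mask.nii.gz"))
    jsonlite::write_json(
      list(totalMl = volume@totalMl, perComponentMl = volume@perComponentMl,
           interiorVoxelMl = volume@interiorVoxelMl,
           partialVoxelMl = volume@partialVoxelMl, method = volume@method,
           thresholds = thresholds, config = configAsList(config)),
      file.path(outDir, "volume.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(out$candidates) && nrow(out$candidates))
      write.csv(out$candidates, file.path(outDir, "candidates.csv"),
                row.names = FALSE)
    saveConfig(config, file.path(outDir, "config.yaml"))
    writeLines(c(sprintf("bone thresholds: [%.6g, %.6g]",
                         thresholds$bone["tLower"], thresholds$bone["tUpper"]),
                 sprintf("fluid threshold: %.6g (pass 1: %.6g)",
                         thresholds$fluid, thresholds$fluidPass1),
                 sprintf("effusion volume: %.4f ml", volume@totalMl)),
               file.path(outDir, "run.log"))
  }
  out
}

#' Run a phantom validation study
#'
#' Delegates to \code{\link{phantomStudy}} (stages 3-4 only, as no bone or
#' other structure is present in the phantom scans) and optionally writes the
#' per-scan volumes (CSV) and a summary embedding the resolved configuration
#' and seeds (JSON).
#'
#' @param kind "CYLINDER_PAIR" or "SPHERE_SHELL".
#' @param nScans number of simulated acquisitions.
#' @param seed base seed; scan i uses seed + i - 1.
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir optional output directory.
#' @return The \code{\link{phantomStudy}} summary list.
#' @export
runPhantomValidation <- function(kind = c("CYLINDER_PAIR", "SPHERE_SHELL"),
                                 nScans = 5L, seed = 0L,
                                 config = effusionConfig(), outDir = NULL) {
  kind <- match.arg(kind)
  spec <- if (kind == "CYLINDER_PAIR") cylinderPhantomSpec(seed = seed)
          else spherePhantomSpec(seed = seed)
  res <- phantomStudy(spec, nScans, baseSeed = seed, config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(data.frame(scan = seq_along(res$volumesMl), seed = res$seeds,
                         volumeMl = res$volumesMl),
              file.path(outDir, sprintf("%s_scans.csv", tolower(kind))),
              row.names = FALSE)
    jsonlite::write_json(
      c(res[c("meanMl", "sdMl", "covPercent", "truthMl", "volumesMl", "seeds")],
        list(kind = kind, config = configAsList(config))),
      file.path(outDir, sprintf("%s_summary.json", tolower(kind))),
      auto_unbox = TRUE, digits = NA)
  }
  res
}
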