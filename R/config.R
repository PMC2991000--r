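#' Default pipeline configuration
#'
#' @param ... named overrides of \linkS4class{PipelineConfig} slots, e.g.
#'   \code{effusionConfig(thresholdMethod = "otsu")}.
#' @return A \linkS4class{PipelineConfig}.
#' @export
effusionConfig <- function(...) {
  cfg <- new("PipelineConfig",
             nBins = 256L, connectivity = 26L, minObjectVoxels = 5L,
             repairAreaFraction = 0.5, contrastSearchDepth = 3L,
             contrastSigma = 1, pouchMarginMm = 15, shellFraction = 0.8,
             shellDistanceVoxels = 2L, subsampling = 5L,
             thresholdMethod = "triangle", anteriorMarginMm = 4,
             vertexPlacement = "interpolated", seed = 0L)
  ov <- list(...)
  for (nm in names(ov)) {
    proto <- slot(cfg, nm)
    slot(cfg, nm) <- if (is.integer(proto)) as.integer(ov[[nm]]) else ov[[nm]]
  }
  validObject(cfg)
  cfg
}

#' Serialize a configuration to a named list / YAML
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return Named list of all slots.
#' @export
configAsList <- function(config) {
  out <- lapply(slotNames(config), function(nm) slot(config, nm))
  names(out) <- slotNames(config)
  out
}

#' Write a configuration as YAML
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' \code{loadConfig(saveConfig(config))} reproduces the configuration
#' exactly.
#'
#' @param path YAML file written by \code{\link{saveConfig}}.
#' @return A \linkS4class{PipelineConfig}.
#' @export
loadConfig <- function(path) {
  do.call(effusionConfig, yaml::read_yaml(path))
}
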