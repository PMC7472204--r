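#' Write a canopy scene to YAML
#'
#' Per-layer blocks `{lai, cab, cca, cw, cdm, cs, n}`, a geometry block,
#' and either a soil albedo or a soil file reference.
#'
#' @param scene a [canopyScene()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScene <- function(scene, path) {
  stopifnot(inherits(scene, "canopyScene"))
  layers <- lapply(scene$layers, function(l)
    list(lai = l$lai, cab = l$leaf$Cab, cca = l$leaf$Cca, cw = l$leaf$Cw,
         cdm = l$leaf$Cdm, cs = l$leaf$Cs, n = l$leaf$N))
  g <- scene$geometry
  obj <- list(layers = layers,
              geometry = list(theta_s = g$theta_s, theta_o = g$theta_o,
                              psi = g$psi, lidf_a = g$lidf_a,
                              lidf_b = g$lidf_b),
              soil = list(wavelength_nm = scene$soil$wavelengths,
                          reflectance = scene$soil$reflectance))
  yaml::write_yaml(obj, path, precision = 12)
  invisible(path)
}

#' Read a canopy scene from YAML
#'
#' @param path file written by [writeScene()].
#' @return A [canopyScene()] object.
#' @export
readScene <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(l)
    canopyLayer(l$lai, leafParams(N = l$n, Cab = l$cab, Cca = l$cca,
                                  Cw = l$cw, Cdm = l$cdm, Cs = l$cs)))
  g <- obj$geometry
  soil <- list(wavelengths = as.numeric(obj$soil$wavelength_nm),
               reflectance = as.numeric(obj$soil$reflectance))
  canopyScene(layers, soil = soil,
              geom = geometry(theta_s = g$theta_s, theta_o = g$theta_o,
                              psi = g$psi, lidf_a = g$lidf_a,
                              lidf_b = g$lidf_b))
}

#' Write simulated spectra to CSV
#'
#' Columns: `wavelength_nm`, `toc_r`, one `layerK_r` per layer, and the
#' per-boundary downward/upward diffuse fluxes.
#'
#' @param output a `spectralOutput` from [simulateCanopy()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(output, path) {
  stopifnot(inherits(output, "spectralOutput"))
  nlay <- nrow(output$layer_top_reflectance)
  tab <- data.frame(wavelength_nm = output$wavelengths,
                    toc_r = output$toc_reflectance)
  for (i in seq_len(nlay))
    tab[[paste0("layer", i, "_r")]] <- output$layer_top_reflectance[i, ]
  for (i in seq_len(nlay + 1)) {
    tab[[paste0("flux_down_", i - 1)]] <-
      output$flux_direct[i, ] + output$flux_down[i, ]
    tab[[paste0("flux_up_", i - 1)]] <- output$flux_up[i, ]
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a scenario set to a directory
#'
#' One YAML scene file per scene plus a `manifest.csv` listing the files
#' and the set metadata.
#'
#' @param set a [scenarioSet()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeScenarioSet <- function(set, dir) {
  stopifnot(inherits(set, "scenarioSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(set$scenes))
  for (i in seq_along(set$scenes)) {
    files[i] <- sprintf("scene_%03d.yaml", i)
    writeScene(set$scenes[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(file = files)
  if (!is.null(set$metadata)) manifest <- cbind(manifest, set$metadata)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write a vegetation-index table to CSV
#'
#' @param vis data frame of VI records (rows = scenes).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVITable <- function(vis, path) {
  utils::write.csv(vis, path, row.names = FALSE)
  invisible(path)
}
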