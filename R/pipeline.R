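#' Experiment run configuration
#'
#' @param experiment one of `"simulate"`, `"layers"`, `"response"`,
#'   `"correlate"`, `"fast"`, `"verify"`.
#' @param seed integer seed recorded in every output manifest.
#' @param out output directory.
#' @param constants `"bundled"`, `"synthetic"`, or a path to a constants
#'   CSV.
#' @param n_layers layer count for `simulate` (1-60).
#' @param options named list of experiment-specific settings (e.g.
#'   `runtimes` for `layers`, `n_scenes` for `verify`).
#' @return An object of class `runConfig`.
#' @export
runConfig <- function(experiment = c("simulate", "layers", "response",
                                     "correlate", "fast", "verify"),
                      seed = 1, out = tempfile("mlcanopy_"),
                      constants = "bundled", n_layers = 3,
                      options = list()) {
  experiment <- match.arg(experiment)
  if (n_layers < 1 || n_layers > 60) stop("n_layers must be in [1, 60]")
  structure(list(experiment = experiment, seed = as.integer(seed),
                 out = out, constants = constants, n_layers = n_layers,
                 options = options),
            class = "runConfig")
}

#' Read/write a run configuration as YAML
#'
#' @param config a [runConfig()] object.
#' @param path YAML file path.
#' @return `readConfig` returns a [runConfig()]; `writeConfig` returns
#'   `path` invisibly.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "runConfig"))
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  runConfig(experiment = obj$experiment, seed = obj$seed, out = obj$out,
            constants = obj$constants, n_layers = obj$n_layers,
            options = if (is.null(obj$options)) list() else obj$options)
}

resolve_constants <- function(spec, grid = seq(400, 2400, by = 1)) {
  if (identical(spec, "bundled")) return(defaultConstants(grid))
  if (identical(spec, "synthetic")) return(syntheticConstants(grid))
  readConstants(spec, grid = grid)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  writeLines(msg, con)
  message(msg)
}

#' Run one of the pipeline experiments end to end
#'
#' Subcommands: `simulate` (standard scene spectra + fluorescence),
#' `layers` (layer-count trials and efficiency selection), `response`
#' (LAI/Cab/Cw sweeps with spectra, first derivatives and VI tables),
#' `correlate` (VI-vs-parameter regression table), `fast` (585-run
#' sensitivity analysis), `verify` (synthetic verification scenes with
#' bias/RMSE between the scene VIs and noise-perturbed replicate VIs).
#' Every run writes a `manifest.csv` with file checksums and a log
#' recording the seed and parameter provenance.
#'
#' @param config a [runConfig()] object.
#' @return The output directory path, invisibly; results are files.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con))
  log_line(con, "experiment=", config$experiment, " seed=", config$seed,
           " constants=", config$constants)
  cs <- resolve_constants(config$constants)
  opt <- config$options

  switch(config$experiment,
    simulate = {
      n <- config$n_layers
      scene <- if (n == 3) threeLayerStandard() else {
        sc <- standardScene()
        lai <- sc$layers[[1]]$lai / n
        canopyScene(replicate(n, canopyLayer(lai, sc$layers[[1]]$leaf),
                              simplify = FALSE), geom = sc$geometry)
      }
      out <- simulateCanopy(scene, cs)
      writeSpectra(out, file.path(config$out, "spectra.csv"))
      sif <- simulateSIF(scene,
                         constants = readConstants_from(cs, 400:850))
      utils::write.csv(data.frame(wavelength_nm = sif$wavelengths,
                                  toc_f = sif$toc_f),
                       file.path(config$out, "sif.csv"), row.names = FALSE)
      writeVITable(computeVIs(out, sif = sif),
                   file.path(config$out, "vi.csv"))
      log_line(con, "simulated ", n, "-layer scene (standard profiles)")
    },
    layers = {
      ref <- layerTrialDefaults()
      runtimes <- opt$runtimes %||% ref$runtime_s
      trials <- runLayerTrials(cs, runtimes = runtimes,
                               measure = isTRUE(opt$measure))
      # reproduction uses the reference (T, A) pairs; computed NDVI errors
      # are opt-in because absolute runtimes and errors are hardware- and
      # coefficient-dependent
      errors <- if (isTRUE(opt$computed_error)) trials$error_A else
        ref$error_A
      sel <- selectLayers(data.frame(n_layers = trials$n_layers,
                                     runtime_s = trials$runtime_s,
                                     error_A = errors))
      report <- data.frame(layers = trials$n_layers,
                           time_s = trials$runtime_s,
                           error = errors,
                           efficiency = 60 / (trials$runtime_s * errors))
      utils::write.csv(report, file.path(config$out, "layer_report.csv"),
                       row.names = FALSE)
      writeLines(as.character(sel), file.path(config$out, "selected_layers.txt"))
      log_line(con, "selected ", sel, " layers (max efficiency)")
    },
    response = {
      sweeps <- list(
        LAI = sweepScenes("LAI", c(0.5, 1, 2, 3, 4, 5, 6)),
        Cab = sweepScenes("Cab", layer_count_table$cab),
        Cw = sweepScenes("Cw", seq(0.005, 0.03, length.out = 7)))
      csf <- readConstants_from(cs, 400:850)
      for (nm in names(sweeps)) {
        set <- sweeps[[nm]]
        vis <- do.call(rbind, lapply(seq_along(set$scenes), function(i) {
          out <- simulateCanopy(set$scenes[[i]], cs)
          sif <- simulateSIF(set$scenes[[i]], constants = csf)
          cbind(set$metadata[i, ], computeVIs(out, sif = sif))
        }))
        writeVITable(vis, file.path(config$out,
                                    paste0("response_", nm, ".csv")))
      }
      log_line(con, "response sweeps written (LAI, Cab, Cw)")
    },
    correlate = {
      tab <- correlationTable(cs)
      utils::write.csv(tab, file.path(config$out, "correlation_fits.csv"),
                       row.names = FALSE)
      log_line(con, "correlation fit table written")
    },
    fast = {
      design <- fastDesign(seed = opt$phase_seed)
      res <- runFAST(design, canopyBandModel(constants = cs))
      X <- fastSample(design)
      utils::write.csv(as.data.frame(X),
                       file.path(config$out, "fast_sample.csv"),
                       row.names = FALSE)
      bands <- colnames(res$s1)
      json <- stats::setNames(lapply(bands, function(b)
        stats::setNames(lapply(rownames(res$s1), function(f)
          list(s1 = res$s1[f, b], st = res$st[f, b])), rownames(res$s1))),
        bands)
      jsonlite::write_json(json, file.path(config$out, "fast_indices.json"),
                           auto_unbox = TRUE, digits = NA)
      tab <- data.frame(factor = rownames(res$s1),
                        s1_560 = res$s1[, 1], s1_685 = res$s1[, 2],
                        s1_810 = res$s1[, 3],
                        st_560 = res$st[, 1], st_685 = res$st[, 2],
                        st_810 = res$st[, 3])
      utils::write.csv(tab, file.path(config$out, "fast_indices.csv"),
                       row.names = FALSE)
      log_line(con, "FAST complete: ", res$n_runs, " runs")
    },
    verify = {
      n <- opt$n_scenes %||% 21
      noise <- opt$noise %||% 0.05
      set <- verificationScenes(n = n, seed = config$seed)
      writeScenarioSet(set, file.path(config$out, "scenes"))
      stats_tab <- verificationStats(set, cs, noise = noise,
                                     seed = config$seed + 1L)
      utils::write.csv(stats_tab$per_vi,
                       file.path(config$out, "verify_stats.csv"),
                       row.names = FALSE)
      log_line(con, "verification stats written for ", n, " scenes")
    })

  files <- setdiff(list.files(config$out, recursive = TRUE), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out, files))),
    seed = config$seed)
  utils::write.csv(manifest, file.path(config$out, "manifest.csv"),
                   row.names = FALSE)
  log_line(con, "manifest written (", length(files), " files)")
  invisible(config$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' VI-vs-parameter correlation fit table
#'
#' Reproduces the correlation-analysis design: uniform sweeps of LAI, Cab
#' and Cw; each vegetation index regressed on its related parameter with
#' the fixed model form (linear for CIgreen, WI, NDWI and
#' WRVI(1600, 820); logarithmic for NDVI, RVI, RVIf, NDVIgreen and
#' WRVI(1450, 1940)).
#'
#' @param constants an [opticalConstants()] object.
#' @param with_sif include the fluorescence ratio rows (slower).
#' @return Data frame with `parameter`, `vi`, `model`, `a`, `b`, `r2`.
#' @export
correlationTable <- function(constants = defaultConstants(),
                             with_sif = TRUE) {
  sweeps <- list(
    LAI = list(set = sweepScenes("LAI", c(0.5, 1, 2, 3, 4, 5, 6)),
               vis = c(ndvi = "log", rvi = "log", rvif = "log")),
    Cab = list(set = sweepScenes("Cab", layer_count_table$cab),
               vis = c(ci_green = "linear", ndvi_green = "log",
                       rvif = "log")),
    Cw = list(set = sweepScenes("Cw", seq(0.005, 0.03, length.out = 7)),
              vis = c(wi = "linear", ndwi = "linear",
                      wrvi_1600_820 = "linear", wrvi_1450_1940 = "log",
                      rvif = "log")))
  csf <- if (with_sif) readConstants_from(constants, 400:850) else NULL
  rows <- list()
  for (par in names(sweeps)) {
    sw <- sweeps[[par]]
    x <- sw$set$metadata$value
    vis <- do.call(rbind, lapply(sw$set$scenes, function(sc) {
      out <- simulateCanopy(sc, constants)
      sif <- if (with_sif) simulateSIF(sc, constants = csf) else NULL
      computeVIs(out, sif = sif)
    }))
    for (vi in names(sw$vis)) {
      if (vi == "rvif" && !with_sif) next
      f <- fitVI(x, vis[[vi]], model = sw$vis[[vi]])
      rows[[length(rows) + 1]] <-
        data.frame(parameter = par, vi = vi, model = f$model,
                   a = f$a, b = f$b, r2 = f$r2)
    }
  }
  do.call(rbind, rows)
}

#' Bias/RMSE verification against perturbed replicates
#'
#' Emulates a field-verification exercise without measured spectra: each
#' scene's VI set is compared with the VI set of a replicate simulation
#' whose layered parameters carry multiplicative lognormal noise
#' (`sdlog = noise`), standing in for measurement error.
#'
#' @param set a [scenarioSet()] of scenes.
#' @param constants an [opticalConstants()] object.
#' @param noise relative perturbation of the layered parameters.
#' @param seed RNG seed for the perturbations.
#' @return List with `per_vi` (data frame: `vi`, `rmse`, `max_abs_bias`,
#'   `min_abs_bias`) and the per-scene VI tables.
#' @export
verificationStats <- function(set, constants = defaultConstants(),
                              noise = 0.05, seed = 1) {
  perturbed <- with_preserved_seed(seed, lapply(set$scenes, function(sc) {
    layers <- lapply(sc$layers, function(l) {
      f <- exp(stats::rnorm(3, 0, noise))
      canopyLayer(l$lai * f[1],
                  standard_leaf(Cab = l$leaf$Cab * f[2],
                                Cw = l$leaf$Cw * f[3]))
    })
    canopyScene(layers, soil = sc$soil, geom = sc$geometry)
  }))
  vi_of <- function(scenes) do.call(rbind, lapply(scenes, function(sc)
    computeVIs(simulateCanopy(sc, constants))))
  sim <- vi_of(set$scenes)
  meas <- vi_of(perturbed)
  cols <- setdiff(names(sim), "rvif")
  per_vi <- do.call(rbind, lapply(cols, function(v) {
    b <- abs(biasError(sim[[v]], meas[[v]]))
    data.frame(vi = v, rmse = rmse(sim[[v]], meas[[v]]),
               max_abs_bias = max(b), min_abs_bias = min(b))
  }))
  list(per_vi = per_vi, simulated = sim, measured = meas)
}
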