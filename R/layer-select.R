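# Reference runtimes and NDVI errors of the seven layer-count trials, used
# as the default inputs of the efficiency selector (runtimes are
# hardware-dependent, so reproduction uses supplied values).
layer_trial_reference <- data.frame(
  n_layers = 1:7,
  runtime_s = c(181.647, 177.311, 182.027, 312.134, 423.791, 446.987,
                493.191),
  error_A = c(0.0037, 0.0051, 0.0026, 0.0018, 0.0015, 0.0045, 0.0101))

#' Reference layer-count trials
#'
#' @return Data frame with `n_layers`, `runtime_s` and `error_A` for the
#'   seven layer-count trials.
#' @export
layerTrialDefaults <- function() layer_trial_reference

#' Signed relative error rate
#'
#' `ER = (mean_value - value) / mean_value`: deviation of a trial value
#' from the multi-trial mean, relative to the mean.
#'
#' @param mean_value reference mean (must be non-zero).
#' @param value trial value.
#' @return Signed relative deviation.
#' @export
errorRate <- function(mean_value, value) {
  if (any(mean_value == 0)) stop("error rate undefined: reference mean is 0")
  (mean_value - value) / mean_value
}

#' Layer-count operating efficiency
#'
#' `E = 1 / ((T/60) * A)`: reciprocal of runtime (converted to minutes)
#' times the absolute vegetation-index error.
#'
#' @param runtime_s runtime in seconds (> 0).
#' @param error_A absolute NDVI deviation from the multi-trial mean (> 0).
#' @return Efficiency score.
#' @export
efficiency <- function(runtime_s, error_A) {
  if (any(runtime_s <= 0)) stop("runtime must be > 0")
  if (any(error_A < 0)) stop("error must be >= 0")
  if (any(error_A == 0))
    stop("infinite efficiency: zero error; exclude such trials explicitly")
  60 / (runtime_s * error_A)
}

#' Select the optimal layer count
#'
#' Computes the efficiency of each trial and returns the layer count with
#' the highest efficiency; ties go to the smallest layer count.  Trials
#' with zero error (infinite efficiency sentinel) are excluded with a
#' warning.
#'
#' @param trials data frame with columns `n_layers`, `runtime_s`,
#'   `error_A` (default: the bundled reference trials).
#' @return Integer: the selected number of layers, with the per-trial
#'   efficiency table as attribute `trials`.
#' @export
selectLayers <- function(trials = layerTrialDefaults()) {
  stopifnot(all(c("n_layers", "runtime_s", "error_A") %in% names(trials)))
  if (nrow(trials) < 2) stop("need at least two trials to select a layer count")
  zero <- trials$error_A == 0
  if (any(zero)) {
    warning(sum(zero), " trial(s) with zero error excluded")
    trials <- trials[!zero, , drop = FALSE]
  }
  if (nrow(trials) == 0) stop("no trials with a discriminating error signal")
  trials$efficiency_E <- efficiency(trials$runtime_s, trials$error_A)
  best <- trials$n_layers[order(-trials$efficiency_E, trials$n_layers)][1]
  structure(as.integer(best), trials = trials)
}

#' Run the layer-count trials through the canopy model
#'
#' Simulates each layer-count scenario, computes its NDVI, derives the
#' error `A = |NDVI_i - mean(NDVI)|`, and combines it with runtimes
#' (supplied, or wall-clock when `measure = TRUE`) into the efficiency
#' table.
#'
#' @param constants an [opticalConstants()] object.
#' @param runtimes runtimes in seconds for the 7 trials; defaults to the
#'   bundled reference values.  Ignored when `measure = TRUE`.
#' @param measure measure wall-clock runtimes instead (live mode).
#' @return Data frame with `n_layers`, `runtime_s`, `ndvi`, `error_A`,
#'   `efficiency_E`.
#' @export
runLayerTrials <- function(constants = defaultConstants(),
                           runtimes = layerTrialDefaults()$runtime_s,
                           measure = FALSE) {
  set <- layerCountScenarios()
  ndvi <- numeric(length(set$scenes))
  times <- numeric(length(set$scenes))
  for (i in seq_along(set$scenes)) {
    t0 <- proc.time()[["elapsed"]]
    out <- simulateCanopy(set$scenes[[i]], constants)
    times[i] <- proc.time()[["elapsed"]] - t0
    ndvi[i] <- computeVIs(out)$ndvi
  }
  if (!measure) times <- runtimes
  A <- abs(ndvi - mean(ndvi))
  ok <- A > 0
  data.frame(n_layers = seq_along(ndvi), runtime_s = times, ndvi = ndvi,
             error_A = A,
             efficiency_E = ifelse(ok, 60 / (times * ifelse(ok, A, NA)),
                                   Inf))
}
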