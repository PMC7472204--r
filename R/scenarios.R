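# Study-condition constants: the standard single-layer parameter set, the
# standard three-layer vertical profiles (top -> bottom), the layer-count
# scenario table and the verification-scene bounds.
standard_values <- list(Cab = 40, Cdm = 0.01, Cw = 0.015, Cs = 0.1,
                        Cca = 10, N = 1.5, LAI = 3,
                        lidf_a = -0.35, lidf_b = -0.15,
                        theta_s = 45, psi = 0)

three_layer_profile <- list(LAI = c(0.75, 1.25, 0.05),
                            Cab = c(80, 60, 40),
                            Cw = c(0.02, 0.021, 0.01))

layer_count_table <- list(
  lai = list(4.78,
             c(2.1, 2.68),
             c(1.5, 2, 1.28),
             c(1.29, 1.32, 1.22, 0.95),
             c(1.2, 0.9, 1.5, 0.68, 0.5),
             c(0.7, 1.02, 0.9, 0.76, 0.8, 0.6),
             c(0.52, 0.62, 0.7, 1.4, 0.54, 0.54, 0.5)),
  cab = c(70, 50, 40, 30, 20, 10, 5),
  cw = 0.009)

verification_bounds <- data.frame(
  factor = c("lai_top", "lai_mid", "lai_low",
             "cab_top", "cab_mid", "cab_low",
             "cw_top", "cw_mid", "cw_low"),
  min = c(0.24, 0.36, 0.14, 30.08, 24.25, 15.86, 0.0076, 0.0080, 0.0082),
  max = c(2.37, 1.97, 1.05, 71.06, 76.17, 55.05, 0.0084, 0.0091, 0.0094),
  mean = c(1.48, 1.42, 0.58, 58.95, 54.30, 37.12, 0.0081, 0.0086, 0.0089))

fast_bounds <- data.frame(
  factor = c("lai_top", "lai_mid", "lai_low",
             "cab_top", "cab_mid", "cab_low",
             "cw_top", "cw_mid", "cw_low"),
  lower = c(1, 0.5, 0.5, 10, 10, 10, 0.001, 0.001, 0.001),
  upper = c(6, 5, 4, 80, 110, 60, 0.03, 0.02, 0.01))

standard_leaf <- function(Cab = standard_values$Cab,
                          Cca = 0.25 * Cab,
                          Cw = standard_values$Cw) {
  leafParams(N = standard_values$N, Cab = Cab, Cca = Cca, Cw = Cw,
             Cdm = standard_values$Cdm, Cs = standard_values$Cs)
}

#' A scenario set: named list of scenes plus provenance metadata
#'
#' @param name label for the set.
#' @param scenes list of [canopyScene()] objects.
#' @param metadata data frame with one row per scene recording the varied
#'   parameter values.
#' @return An object of class `scenarioSet`.
#' @export
scenarioSet <- function(name, scenes, metadata = NULL) {
  structure(list(name = name, scenes = scenes, metadata = metadata),
            class = "scenarioSet")
}

#' @export
print.scenarioSet <- function(x, ...) {
  cat("Scenario set '", x$name, "': ", length(x$scenes), " scene(s)\n",
      sep = "")
  invisible(x)
}

#' Standard single-layer scene
#'
#' One homogeneous layer at the standard parameter values: Cab 40, Cca 10,
#' Cw 0.015 cm, Cdm 0.01, Cs 0.1, N 1.5, LAI 3, LIDF (-0.35, -0.15), sun
#' zenith 45 degrees, nadir view.
#'
#' @return A [canopyScene()] object.
#' @export
standardScene <- function() {
  sv <- standard_values
  canopyScene(
    canopyLayer(sv$LAI, leafParams(N = sv$N, Cab = sv$Cab, Cca = sv$Cca,
                                   Cw = sv$Cw, Cdm = sv$Cdm, Cs = sv$Cs)),
    geom = geometry(theta_s = sv$theta_s, psi = sv$psi,
                    lidf_a = sv$lidf_a, lidf_b = sv$lidf_b))
}

#' Standard three-layer vertically heterogeneous scene
#'
#' Top-to-bottom profiles: LAI (0.75, 1.25, 0.05), Chla+b (80, 60, 40),
#' Cw (0.02, 0.021, 0.01) cm, with carotenoids at 25% of Chla+b per layer
#' and the remaining parameters at their standard values.
#'
#' @return A [canopyScene()] object with three layers.
#' @export
threeLayerStandard <- function() {
  p <- three_layer_profile
  layers <- lapply(1:3, function(i)
    canopyLayer(p$LAI[i], standard_leaf(Cab = p$Cab[i], Cw = p$Cw[i])))
  canopyScene(layers, geom = geometry())
}

#' Layer-count scenarios (1 to 7 layers)
#'
#' Scene i has i layers with the i-th row of the layer-count design: the
#' listed per-layer LAI values top to bottom, a single Chla+b value applied
#' to all layers (70, 50, 40, 30, 20, 10, 5 for 1-7 layers), water content
#' fixed at 0.009 cm, and all other parameters standard.
#'
#' @return A [scenarioSet()] of 7 scenes.
#' @export
layerCountScenarios <- function() {
  tab <- layer_count_table
  scenes <- lapply(1:7, function(i) {
    leaf <- standard_leaf(Cab = tab$cab[i], Cw = tab$cw)
    layers <- lapply(tab$lai[[i]], canopyLayer, leaf = leaf)
    canopyScene(layers, geom = geometry())
  })
  meta <- data.frame(
    n_layers = 1:7,
    total_lai = vapply(tab$lai, sum, numeric(1)),
    cab = tab$cab, cw = tab$cw)
  scenarioSet("layer_count", scenes, meta)
}

with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# truncated-normal quantile
qtnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Synthetic verification scenes
#'
#' Samples `n` three-layer scenes whose nine layered parameters (LAI,
#' Chla+b, Cw per layer) each follow a truncated normal within the
#' verification bounds, centred on the tabulated means with sd set to 1/6
#' of the range.  Layers of the same variable are coupled through a
#' Gaussian copula with correlation 0.7 so that dense scenes are dense
#' throughout.  The returned set is ordered from dense to sparse (total LAI
#' decreasing).
#'
#' @param n number of scenes (default 21).
#' @param seed RNG seed (required; the set is reproducible).
#' @return A [scenarioSet()] with `metadata` holding the sampled values.
#' @export
verificationScenes <- function(n = 21, seed) {
  if (missing(seed)) stop("a seed is required for reproducible scenes")
  vb <- verification_bounds
  draw <- with_preserved_seed(seed, {
    vals <- matrix(0, n, 9, dimnames = list(NULL, vb$factor))
    for (v in c("lai", "cab", "cw")) {
      common <- stats::rnorm(n)
      for (j in 1:3) {
        z <- sqrt(0.7) * common + sqrt(0.3) * stats::rnorm(n)
        u <- stats::pnorm(z)
        f <- paste0(v, "_", c("top", "mid", "low")[j])
        row <- vb[vb$factor == f, ]
        vals[, f] <- qtnorm(u, row$mean, (row$max - row$min) / 6,
                            row$min, row$max)
      }
    }
    vals
  })
  total_lai <- rowSums(draw[, 1:3])
  ord <- order(total_lai, decreasing = TRUE)
  draw <- draw[ord, , drop = FALSE]
  scenes <- lapply(seq_len(n), function(i) {
    layers <- lapply(1:3, function(j) {
      pos <- c("top", "mid", "low")[j]
      canopyLayer(draw[i, paste0("lai_", pos)],
                  standard_leaf(Cab = draw[i, paste0("cab_", pos)],
                                Cw = draw[i, paste0("cw_", pos)]))
    })
    canopyScene(layers, geom = geometry())
  })
  meta <- as.data.frame(draw)
  meta$total_lai <- rowSums(draw[, 1:3])
  scenarioSet("verification", scenes, meta)
}

sweep_ranges <- list(LAI = c(0, 6), Cab = c(0, 110), Cw = c(0, 0.07))

#' Single-parameter scenario sweep
#'
#' One scene per value of the swept parameter; every other parameter stays
#' at its standard value and carotenoids track chlorophyll at 25%.  In
#' `uniform` mode the scene is a single homogeneous layer; in `layered`
#' mode the standard three-layer profile of the parameter is rescaled so
#' that its total (LAI) or its per-layer values (Cab, Cw, scaled
#' proportionally) match the requested value.
#'
#' @param parameter one of `"LAI"`, `"Cab"`, `"Cw"`.
#' @param values numeric vector of sweep values.
#' @param mode `"uniform"` (default) or `"layered"`.
#' @return A [scenarioSet()].
#' @export
sweepScenes <- function(parameter = c("LAI", "Cab", "Cw"), values,
                        mode = c("uniform", "layered")) {
  parameter <- match.arg(parameter)
  mode <- match.arg(mode)
  rng <- sweep_ranges[[parameter]]
  if (length(values) && any(values < rng[1] | values > rng[2]))
    warning(parameter, " sweep values outside the guidance range [",
            rng[1], ", ", rng[2], "]")
  scenes <- lapply(values, function(v) {
    if (mode == "uniform") {
      lai <- if (parameter == "LAI") v else standard_values$LAI
      cab <- if (parameter == "Cab") v else standard_values$Cab
      cw <- if (parameter == "Cw") v else standard_values$Cw
      canopyScene(canopyLayer(lai, standard_leaf(Cab = cab, Cw = cw)),
                  geom = geometry())
    } else {
      p <- three_layer_profile
      scale_lai <- if (parameter == "LAI") v / sum(p$LAI) else 1
      scale_cab <- if (parameter == "Cab") v / mean(p$Cab) else 1
      scale_cw <- if (parameter == "Cw") v / mean(p$Cw) else 1
      layers <- lapply(1:3, function(j)
        canopyLayer(p$LAI[j] * scale_lai,
                    standard_leaf(Cab = p$Cab[j] * scale_cab,
                                  Cw = p$Cw[j] * scale_cw)))
      canopyScene(layers, geom = geometry())
    }
  })
  meta <- if (length(values)) {
    data.frame(parameter = parameter, value = values, mode = mode)
  } else {
    data.frame(parameter = character(), value = numeric(),
               mode = character())
  }
  scenarioSet(paste0("sweep_", parameter), scenes, meta)
}
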