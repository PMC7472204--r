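#' Canopy layer
#'
#' @param lai layer leaf area index (m2/m2, >= 0).
#' @param leaf a [leafParams()] object describing the layer's leaves.
#' @return An object of class `canopyLayer`.
#' @export
canopyLayer <- function(lai, leaf = leafParams()) {
  lai <- as.numeric(lai)[1]
  if (!is.finite(lai) || lai < 0) stop("layer LAI must be >= 0")
  stopifnot(inherits(leaf, "leafParams"))
  structure(list(lai = lai, leaf = leaf), class = "canopyLayer")
}

#' Soil background reflectance
#'
#' Generic smooth dry-soil spectrum increasing from 0.05 at 400 nm to 0.35
#' at 2400 nm, or a constant albedo when `albedo` is given.
#'
#' @param grid wavelength grid (nm).
#' @param albedo optional constant albedo in `[0, 1]`.
#' @return List with `wavelengths` and `reflectance`.
#' @export
soilSpectrum <- function(grid = seq(400, 2400, by = 1), albedo = NULL) {
  r <- if (is.null(albedo)) {
    0.05 + 0.30 * (grid - 400) / 2000
  } else {
    if (albedo < 0 || albedo > 1) stop("soil albedo must lie in [0, 1]")
    rep(albedo, length(grid))
  }
  list(wavelengths = grid, reflectance = pmin(pmax(r, 0), 1))
}

#' Multilayer canopy scene
#'
#' @param layers list of [canopyLayer()] objects ordered top to bottom
#'   (1 to 60 layers).
#' @param soil soil background from [soilSpectrum()] (interpolated onto the
#'   simulation grid) or a single albedo value.
#' @param geom a [geometry()] object.
#' @return An object of class `canopyScene`.
#' @export
canopyScene <- function(layers, soil = soilSpectrum(), geom = geometry()) {
  if (inherits(layers, "canopyLayer")) layers <- list(layers)
  if (length(layers) < 1 || length(layers) > 60)
    stop("a scene must have between 1 and 60 layers")
  for (l in layers) stopifnot(inherits(l, "canopyLayer"))
  if (is.numeric(soil) && length(soil) == 1) soil <- soilSpectrum(albedo = soil)
  if (any(soil$reflectance < 0 | soil$reflectance > 1))
    stop("soil reflectance must lie in [0, 1]")
  stopifnot(inherits(geom, "geometry"))
  structure(list(layers = layers, soil = soil, geometry = geom),
            class = "canopyScene")
}

#' @export
print.canopyScene <- function(x, ...) {
  cat("Canopy scene:", length(x$layers), "layer(s), total LAI =",
      round(sum(vapply(x$layers, `[[`, numeric(1), "lai")), 3), "\n")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: LAI=%.3g Cab=%.3g Cw=%.4g\n",
                i, l$lai, l$leaf$Cab, l$leaf$Cw))
  }
  invisible(x)
}

# Vectorized J-functions of the SAIL layer solution, guarded near k = m.
Jfunc1 <- function(k, m, t) {
  ekt <- exp(-k * t)
  del <- (k - m) * t
  out <- numeric(length(del))
  big <- abs(del) > 1e-3
  out[big] <- (exp(-m[big] * t) - ekt) / (k - m[big])
  if (any(!big))
    out[!big] <- 0.5 * t * (ekt + exp(-m[!big] * t)) * (1 - del[!big]^2 / 12)
  out
}
Jfunc2 <- function(k, m, t) (1 - exp(-(k + m) * t)) / (k + m)

# Four-stream operator of one homogeneous layer: direct transmittance tss,
# direct-to-diffuse tsd/rsd, diffuse tdd/rdd.  Uses the analytic
# two-stream/SAIL solution, with an exact conservative-limit branch where
# the diffuse eigenvalue m vanishes (rho + tau = 1).
layer_operator <- function(coef, lai) {
  nwl <- length(coef$att)
  if (lai <= 0) {
    one <- rep(1, nwl); zero <- rep(0, nwl)
    return(list(tss = one, tsd = zero, tdd = one, rsd = zero, rdd = zero))
  }
  ks <- coef$ks
  m <- coef$m; att <- coef$att; sigb <- coef$sigb
  sb <- coef$sb; sf <- coef$sf
  tss <- rep(exp(-ks * lai), nwl)

  tsd <- rsd <- tdd <- rdd <- numeric(nwl)
  cons <- m < 1e-7
  gen <- !cons
  if (any(gen)) {
    mg <- m[gen]
    rinf <- ifelse(sigb[gen] > 0, (att[gen] - mg) / sigb[gen], 0)
    e1 <- exp(-mg * lai); e2 <- e1^2
    re <- rinf * e1
    denom <- 1 - rinf^2 * e2
    J1ks <- Jfunc1(ks, mg, lai)
    J2ks <- Jfunc2(ks, mg, lai)
    Ps <- (sf[gen] + sb[gen] * rinf) * J1ks
    Qs <- (sf[gen] * rinf + sb[gen]) * J2ks
    rdd[gen] <- rinf * (1 - e2) / denom
    tdd[gen] <- (1 - rinf^2) * e1 / denom
    tsd[gen] <- (Ps - re * Qs) / denom
    rsd[gen] <- (Qs - re * Ps) / denom
  }
  if (any(cons)) {
    # exact solution of the conservative two-stream system (att = sigb = c)
    cc <- sigb[cons]
    sfc <- sf[cons]; sbc <- sb[cons]
    tssc <- exp(-ks * lai)
    FL <- (sfc + sbc) * (1 - tssc) / ks
    H <- (sfc - sbc) * (1 - tssc) / ks
    Gi <- (sfc + sbc) / ks * (lai - (1 - tssc) / ks)
    rsd[cons] <- (FL - H + 2 * cc * Gi) / (2 * (1 + cc * lai))
    tsd[cons] <- FL - rsd[cons]
    rdd[cons] <- cc * lai / (1 + cc * lai)
    tdd[cons] <- 1 / (1 + cc * lai)
  }
  list(tss = tss, tsd = pmax(tsd, 0), tdd = pmax(tdd, 0),
       rsd = pmax(rsd, 0), rdd = pmax(rdd, 0))
}

#' Combine a layer with the stack below it (adding method)
#'
#' Closes the multiple reflections between a layer operator and the
#' reflectance operator of everything below it by the geometric-series
#' factor `1 / (1 - rdd_layer * rdd_below)`.
#'
#' @param layer four-stream operator of the upper layer (list with `tss`,
#'   `tsd`, `tdd`, `rsd`, `rdd`).
#' @param below operator of the lower stack (same fields; transmittances of
#'   the soil operator are zero).
#' @return Combined operator of layer-over-stack.
#' @export
addLayer <- function(layer, below) {
  series <- layer$rdd * below$rdd
  if (any(series >= 1))
    stop("adding series diverges: layer and lower-stack reflectances >= 1")
  denom <- 1 - series
  d <- (layer$tsd + layer$rdd * below$rsd * layer$tss) / denom
  u <- below$rsd * layer$tss + below$rdd * d
  dd <- layer$tdd / denom
  ud <- below$rdd * dd
  list(tss = layer$tss * below$tss,
       tsd = below$tsd * layer$tss + below$tdd * d,
       tdd = below$tdd * dd,
       rsd = layer$rsd + layer$tdd * u,
       rdd = layer$rdd + layer$tdd * ud)
}

soil_operator <- function(refl) {
  zero <- numeric(length(refl))
  list(tss = zero, tsd = zero, tdd = zero, rsd = refl, rdd = refl)
}

# Leaf spectra cache keyed by the parameter values, so sweeps and
# homogeneous multilayer scenes compute each distinct leaf only once.
leaf_spectra_for <- function(layers, constants) {
  keys <- vapply(layers, function(l)
    paste(unlist(l$leaf), collapse = "|"), character(1))
  uniq <- !duplicated(keys)
  cache <- lapply(layers[uniq], function(l) plateRT(l$leaf, constants))
  names(cache) <- keys[uniq]
  lapply(keys, function(k) cache[[k]])
}

#' Simulate top-of-canopy reflectance and flux profiles
#'
#' Runs the multilayer four-stream model: leaf spectra from the plate
#' model, SAIL-type layer coefficients, bottom-up adding for reflectance
#' and top-down peeling for the per-boundary flux profile under unit direct
#' top-of-canopy irradiance.
#'
#' @param scene a [canopyScene()] object.
#' @param constants an [opticalConstants()] object; its grid defines the
#'   simulation wavelengths.
#' @return An object of class `spectralOutput`: list with `wavelengths`,
#'   `toc_reflectance` (directional-hemispherical reflectance for direct
#'   sun), `layer_top_reflectance` (matrix, one row per layer: reflectance
#'   of the sub-stack from that layer's top downward, soil included),
#'   `flux_direct`, `flux_down`, `flux_up` (matrices over boundaries 0..N),
#'   `absorbed` (per-layer absorbed flux), `soil_absorbed`, and the scene.
#' @export
simulateCanopy <- function(scene, constants = defaultConstants()) {
  stopifnot(inherits(scene, "canopyScene"),
            inherits(constants, "opticalConstants"))
  grid <- constants$wavelengths
  soil <- stats::approx(scene$soil$wavelengths, scene$soil$reflectance,
                        xout = grid, rule = 2)$y
  geo <- sail_geometry(scene$geometry)
  leaves <- leaf_spectra_for(scene$layers, constants)
  nlay <- length(scene$layers)

  ops <- vector("list", nlay)
  for (i in seq_len(nlay)) {
    coef <- layerCoefficients(leaves[[i]], scene$geometry, geo = geo)
    ops[[i]] <- layer_operator(coef, scene$layers[[i]]$lai)
  }

  # bottom-up adding: sub[[i]] is the operator of layers i..N plus soil
  sub <- vector("list", nlay + 1)
  sub[[nlay + 1]] <- soil_operator(soil)
  for (i in rev(seq_len(nlay))) sub[[i]] <- addLayer(ops[[i]], sub[[i + 1]])

  # top-down peeling: boundary fluxes under unit direct TOC irradiance
  nwl <- length(grid)
  Es <- matrix(0, nlay + 1, nwl)
  Ed <- matrix(0, nlay + 1, nwl)
  Eu <- matrix(0, nlay + 1, nwl)
  Es[1, ] <- 1
  Eu[1, ] <- sub[[1]]$rsd
  for (i in seq_len(nlay)) {
    op <- ops[[i]]
    Rsd_b <- sub[[i + 1]]$rsd; Rdd_b <- sub[[i + 1]]$rdd
    Es[i + 1, ] <- op$tss * Es[i, ]
    denom <- 1 - op$rdd * Rdd_b
    Ed[i + 1, ] <- (op$tsd * Es[i, ] + op$tdd * Ed[i, ] +
                      op$rdd * Rsd_b * Es[i + 1, ]) / denom
    Eu[i + 1, ] <- Rsd_b * Es[i + 1, ] + Rdd_b * Ed[i + 1, ]
  }
  absorbed <- matrix(0, nlay, nwl)
  for (i in seq_len(nlay)) {
    absorbed[i, ] <- (Es[i, ] + Ed[i, ] + Eu[i + 1, ]) -
      (Es[i + 1, ] + Ed[i + 1, ] + Eu[i, ])
  }
  soil_absorbed <- (Es[nlay + 1, ] + Ed[nlay + 1, ]) * (1 - soil)

  layer_top <- do.call(rbind, lapply(seq_len(nlay),
                                     function(i) sub[[i]]$rsd))
  structure(list(wavelengths = grid,
                 toc_reflectance = sub[[1]]$rsd,
                 layer_top_reflectance = layer_top,
                 flux_direct = Es, flux_down = Ed, flux_up = Eu,
                 absorbed = absorbed, soil_absorbed = soil_absorbed,
                 soil_reflectance = soil,
                 operators = ops, substacks = sub,
                 scene = scene),
            class = "spectralOutput")
}

#' @export
print.spectralOutput <- function(x, ...) {
  cat(sprintf(
    "Spectral output: %d wavelengths (%g-%g nm), %d layer(s), TOC reflectance in [%.3f, %.3f]\n",
    length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
    nrow(x$layer_top_reflectance), min(x$toc_reflectance),
    max(x$toc_reflectance)))
  invisible(x)
}
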