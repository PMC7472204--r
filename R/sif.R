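#' Incident top-of-canopy irradiance
#'
#' Smooth solar-like spectrum (5800 K Planck shape) in relative units,
#' normalized so that the integral over the photosynthetically active
#' region 400-700 nm equals `par`.
#'
#' @param par photosynthetically active radiation scale (default 1200,
#'   relative units mirroring umol m-2 s-1).
#' @param grid wavelength grid (nm), default 400-850.
#' @return List with `wavelengths`, `spectrum` and `par`.
#' @export
irradiance <- function(par = 1200, grid = seq(400, 850, by = 1)) {
  if (par < 0) stop("par must be >= 0")
  x <- 1.43877e7 / (grid * 5800)
  planck <- grid^-5 / (exp(x) - 1)
  step <- if (length(grid) > 1) mean(diff(grid)) else 1
  pars <- grid >= 400 & grid <= 700
  scale <- par / sum(planck[pars] * step)
  list(wavelengths = grid, spectrum = planck * scale, par = par)
}

subset_constants <- function(constants, wl) {
  idx <- match(wl, constants$wavelengths)
  if (anyNA(idx))
    stop("requested wavelengths are not all on the constants grid")
  opticalConstants(wl, constants$n[idx], constants$k_cab[idx],
                   constants$k_cca[idx], constants$k_cw[idx],
                   constants$k_cdm[idx], constants$k_cs[idx])
}

# diffuse operators (tdd, rdd only) of one layer at the emission grid
diffuse_ops <- function(scene, constants, lai_scale = 1) {
  geo <- sail_geometry(scene$geometry)
  leaves <- leaf_spectra_for(scene$layers, constants)
  lapply(seq_along(scene$layers), function(i) {
    coef <- layerCoefficients(leaves[[i]], scene$geometry, geo = geo)
    layer_operator(coef, scene$layers[[i]]$lai * lai_scale)
  })
}

#' Simulate top-of-canopy sun-induced fluorescence
#'
#' Each layer's absorbed excitation flux (400-750 nm, from the canopy flux
#' profile under the given irradiance) is converted to an emission spectrum
#' through the fluorescence efficiencies and fixed emission basis spectra,
#' split equally into upward and downward hemispheres at the layer
#' boundaries (attenuated through half the emitting layer), and propagated
#' to the top of the canopy through the diffuse layer operators at the
#' emission wavelengths, including multiple reflections between each source
#' boundary and the stacks above and below it.  Re-excitation by emitted
#' photons is neglected.
#'
#' @param scene a [canopyScene()] object.
#' @param fp a [fluorescenceParams()] object.
#' @param irr incident irradiance from [irradiance()].
#' @param constants an [opticalConstants()] object covering 400-850 nm at
#'   1 nm.
#' @param emission emission wavelength grid (nm), default 640-850.
#' @return An object of class `sifSpectrum`: list with `wavelengths`
#'   (emission grid) and `toc_f` (fluorescence radiant flux, relative
#'   units).
#' @export
simulateSIF <- function(scene, fp = fluorescenceParams(),
                        irr = irradiance(),
                        constants = defaultConstants(seq(400, 850, 1)),
                        emission = seq(640, 850, by = 1)) {
  stopifnot(inherits(scene, "canopyScene"),
            inherits(fp, "fluorescenceParams"))
  excitation <- constants$wavelengths[constants$wavelengths >= 400 &
                                        constants$wavelengths <= 750]
  cx <- subset_constants(constants, excitation)
  out <- simulateCanopy(scene, cx)
  I <- stats::approx(irr$wavelengths, irr$spectrum, xout = excitation,
                     rule = 2)$y
  step_x <- if (length(excitation) > 1) mean(diff(excitation)) else 1
  nlay <- length(scene$layers)
  # total absorbed excitation flux per layer
  abs_flux <- as.numeric(out$absorbed %*% (I * step_x))

  shapes <- lapply(scene$layers, function(l)
    emission_shape(l$leaf, fp, constants, emission))

  cf <- subset_constants(constants, emission)
  ops_f <- diffuse_ops(scene, cf)
  ops_half <- diffuse_ops(scene, cf, lai_scale = 0.5)

  # bottom stacks: diffuse reflectance of layers i..N plus soil
  soil <- stats::approx(scene$soil$wavelengths, scene$soil$reflectance,
                        xout = emission, rule = 2)$y
  Rsub <- vector("list", nlay + 1)
  Rsub[[nlay + 1]] <- soil
  for (i in rev(seq_len(nlay))) {
    op <- ops_f[[i]]
    Rsub[[i]] <- op$rdd + op$tdd^2 * Rsub[[i + 1]] /
      (1 - op$rdd * Rsub[[i + 1]])
  }
  # top stacks: transmission through and reflectance from below of 1..j
  Ttop <- vector("list", nlay + 1)   # index j+1 holds stack 1..j
  Rbot <- vector("list", nlay + 1)
  Ttop[[1]] <- rep(1, length(emission))
  Rbot[[1]] <- rep(0, length(emission))
  for (j in seq_len(nlay)) {
    op <- ops_f[[j]]
    denom <- 1 - Rbot[[j]] * op$rdd
    Ttop[[j + 1]] <- Ttop[[j]] * op$tdd / denom
    Rbot[[j + 1]] <- op$rdd + op$tdd^2 * Rbot[[j]] / denom
  }

  toc_f <- numeric(length(emission))
  for (i in seq_len(nlay)) {
    src <- abs_flux[i] * shapes[[i]]
    th <- ops_half[[i]]$tdd
    up <- 0.5 * src * th
    dn <- 0.5 * src * th
    toc_f <- toc_f +
      Ttop[[i]] * up / (1 - Rbot[[i]] * Rsub[[i]]) +
      Ttop[[i + 1]] * Rsub[[i + 1]] * dn /
        (1 - Rbot[[i + 1]] * Rsub[[i + 1]])
  }
  structure(list(wavelengths = emission, toc_f = pmax(toc_f, 0)),
            class = "sifSpectrum")
}

#' @export
print.sifSpectrum <- function(x, ...) {
  pk <- x$wavelengths[which.max(x$toc_f)]
  cat(sprintf("SIF spectrum: %g-%g nm, peak at %g nm\n",
              min(x$wavelengths), max(x$wavelengths), pk))
  invisible(x)
}

#' Fluorescence ratio index F685/F730
#'
#' @param sif a `sifSpectrum` object from [simulateSIF()].
#' @return The ratio of fluorescence at 685 nm to 730 nm.
#' @export
rvif <- function(sif) {
  f685 <- band(sif$toc_f, 685, sif$wavelengths)
  f730 <- band(sif$toc_f, 730, sif$wavelengths)
  if (f730 == 0) stop("undefined fluorescence ratio: F(730) = 0")
  f685 / f730
}
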