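#' Leaf biochemical parameters
#'
#' @param N leaf mesophyll structure parameter (dimensionless, >= 1; the
#'   usual range is 1-3 and values outside it trigger a warning).
#' @param Cab chlorophyll a+b content (ug/cm2).
#' @param Cca carotenoid content (ug/cm2).
#' @param Cw equivalent water thickness (cm).
#' @param Cdm dry matter content (g/cm2).
#' @param Cs senescent brown-pigment fraction (dimensionless).
#' @return An object of class `leafParams`.
#' @export
leafParams <- function(N = 1.5, Cab = 40, Cca = 10, Cw = 0.015,
                       Cdm = 0.01, Cs = 0.1) {
  vals <- c(N = as.numeric(N)[1], Cab = as.numeric(Cab)[1],
            Cca = as.numeric(Cca)[1], Cw = as.numeric(Cw)[1],
            Cdm = as.numeric(Cdm)[1], Cs = as.numeric(Cs)[1])
  if (any(!is.finite(vals))) stop("leaf parameters must be finite")
  if (N < 1) stop("leaf structure parameter N must be >= 1")
  if (N > 3) warning("N = ", N, " is outside the usual 1-3 range")
  if (any(vals[-1] < 0)) stop("leaf constituent contents must be >= 0")
  structure(as.list(vals), class = "leafParams")
}

#' @export
print.leafParams <- function(x, ...) {
  cat(sprintf(
    "Leaf: N=%.2f Cab=%.3g Cca=%.3g Cw=%.4g Cdm=%.4g Cs=%.3g\n",
    x$N, x$Cab, x$Cca, x$Cw, x$Cdm, x$Cs))
  invisible(x)
}

#' Fluorescence quantum efficiencies
#'
#' @param eps1 photosystem I fluorescence quantum efficiency (default 0.004).
#' @param eps2 photosystem II fluorescence quantum efficiency (default 0.02).
#' @return An object of class `fluorescenceParams`.
#' @export
fluorescenceParams <- function(eps1 = 0.004, eps2 = 0.02) {
  if (eps1 < 0 || eps1 > 0.1 || eps2 < 0 || eps2 > 0.1)
    stop("fluorescence efficiencies must lie in [0, 0.1]")
  structure(list(eps1 = eps1, eps2 = eps2), class = "fluorescenceParams")
}

#' Per-elementary-layer absorption coefficient
#'
#' Linear mixing of the constituent specific absorption spectra, divided by
#' the structure parameter N so that the coefficient refers to one
#' elementary plate of the leaf.
#'
#' @param params a [leafParams()] object.
#' @param constants an [opticalConstants()] object.
#' @return Numeric absorption coefficient spectrum (one value per grid
#'   wavelength, >= 0).
#' @export
totalAbsorption <- function(params, constants) {
  stopifnot(inherits(params, "leafParams"),
            inherits(constants, "opticalConstants"))
  (params$Cab * constants$k_cab + params$Cca * constants$k_cca +
     params$Cw * constants$k_cw + params$Cdm * constants$k_cdm +
     params$Cs * constants$k_cs) / params$N
}

# Diffuse transmission through one elementary absorbing plate:
# integral over the hemisphere of exp(-k/mu), which has the closed form
# (1-k) exp(-k) + k^2 E1(k).
plate_transmission <- function(k) {
  out <- rep(1, length(k))
  pos <- k > 0
  if (any(pos)) {
    kk <- k[pos]
    out[pos] <- (1 - kk) * exp(-kk) + kk^2 * pracma::expint(kk)
  }
  pmin(pmax(out, 0), 1)
}

# Average transmissivity of a dielectric interface for radiation incident
# within a cone of half-angle alpha (deg), by numerical quadrature of the
# Fresnel transmittance weighted by sin(theta) cos(theta).
tav <- function(alpha, n, n_quad = 256) {
  a <- alpha * pi / 180
  th <- (seq_len(n_quad) - 0.5) / n_quad * a
  w <- sin(th) * cos(th)
  sapply(n, function(ni) {
    sin_t <- sin(th) / ni
    cos_t <- sqrt(pmax(1 - sin_t^2, 0))
    rs <- ((cos(th) - ni * cos_t) / (cos(th) + ni * cos_t))^2
    rp <- ((ni * cos(th) - cos_t) / (ni * cos(th) + cos_t))^2
    tf <- 1 - 0.5 * (rs + rp)
    sum(tf * w) / sum(w)
  })
}

#' Leaf reflectance and transmittance from the generalized plate model
#'
#' The leaf is modelled as N identical absorbing plates separated by air
#' gaps.  The top interface receives radiation within a 40 degree cone;
#' internal interfaces are illuminated diffusely (90 degrees).  Plate
#' transmission uses the exponential-integral hemispherical attenuation and
#' the stack of N plates is closed analytically (Stokes system).
#'
#' @param params a [leafParams()] object.
#' @param constants an [opticalConstants()] object.
#' @return An object of class `leafSpectra`: list with `wavelengths`, `rho`
#'   (hemispherical reflectance) and `tau` (hemispherical transmittance).
#' @export
plateRT <- function(params, constants) {
  stopifnot(inherits(params, "leafParams"),
            inherits(constants, "opticalConstants"))
  N <- params$N
  if (N < 1) stop("N must be >= 1")
  k <- totalAbsorption(params, constants)
  theta <- plate_transmission(k)
  n <- constants$n

  talf <- tav(40, n)
  ralf <- 1 - talf
  t12 <- tav(90, n)
  r12 <- 1 - t12
  t21 <- t12 / n^2
  r21 <- 1 - t21

  denom <- 1 - r21^2 * theta^2
  Ta <- talf * theta * t21 / denom
  Ra <- ralf + r21 * theta * Ta
  t <- t12 * theta * t21 / denom
  r <- r12 + r21 * theta * t

  # Stokes extension from one plate to N plates (the remaining N-1 are
  # internal, diffusely illuminated)
  Rsub <- numeric(length(k))
  Tsub <- numeric(length(k))
  cons <- r + t >= 1 - 1e-12          # non-absorbing: degenerate discriminant
  if (any(cons)) {
    tc <- t[cons]
    Tsub[cons] <- tc / (tc + (1 - tc) * (N - 1))
    Rsub[cons] <- 1 - Tsub[cons]
  }
  gen <- !cons
  if (any(gen)) {
    rg <- r[gen]; tg <- t[gen]
    D <- sqrt(pmax((1 + rg + tg) * (1 + rg - tg) *
                     (1 - rg + tg) * (1 - rg - tg), 0))
    rq <- rg^2; tq <- tg^2
    a <- (1 + rq - tq + D) / (2 * rg)
    b <- (1 - rq + tq + D) / (2 * tg)
    bNm1 <- b^(N - 1)
    bN2 <- bNm1^2
    a2 <- a^2
    den2 <- a2 * bN2 - 1
    Rsub[gen] <- a * (bN2 - 1) / den2
    Tsub[gen] <- bNm1 * (a2 - 1) / den2
  }
  den3 <- 1 - Rsub * r
  tau <- Ta * Tsub / den3
  rho <- Ra + Ta * Rsub * t / den3

  structure(list(wavelengths = constants$wavelengths,
                 rho = pmin(pmax(rho, 0), 1),
                 tau = pmin(pmax(tau, 0), 1)),
            class = "leafSpectra")
}

#' @export
print.leafSpectra <- function(x, ...) {
  cat(sprintf("Leaf spectra: %d wavelengths, rho in [%.3f, %.3f], tau in [%.3f, %.3f]\n",
              length(x$wavelengths), min(x$rho), max(x$rho),
              min(x$tau), max(x$tau)))
  invisible(x)
}

# Per-leaf emission envelope: efficiency-weighted basis spectra times the
# within-leaf reabsorption escape factor, the interior transmission over
# half the elementary-plate absorption depth at the emission wavelength
# (photons are emitted throughout the leaf, so the mean escape path is
# half a plate).
emission_shape <- function(params, fp, constants, emission) {
  k <- totalAbsorption(params, constants)
  idx <- match(emission, constants$wavelengths)
  if (anyNA(idx))
    stop("emission grid must be a subset of the constants grid")
  esc <- plate_transmission(k[idx] / 2)
  bases <- fluorescence_bases(emission)
  (fp$eps1 * bases$psi + fp$eps2 * bases$psii) * esc
}

# Unit-area fluorescence emission basis spectra on an emission grid (nm).
# basisPSII peaks at 685 nm with a secondary 735 nm band; basisPSI peaks at
# 740 nm.  Both integrate to 1 over the grid.
fluorescence_bases <- function(emission) {
  g <- function(mu, s) exp(-0.5 * ((emission - mu) / s)^2)
  psii <- 0.55 * g(685, 10) / (10 * sqrt(2 * pi)) +
    0.45 * g(735, 32) / (32 * sqrt(2 * pi))
  psi <- g(740, 28) / (28 * sqrt(2 * pi))
  step <- if (length(emission) > 1) mean(diff(emission)) else 1
  list(psi = psi / sum(psi * step), psii = psii / sum(psii * step))
}

#' Leaf fluorescence excitation-emission matrices
#'
#' Simplified excitation-emission matrices: for each excitation wavelength
#' the emitted spectrum is the leaf's absorbed fraction at that wavelength
#' times `eps1 * basisPSI + eps2 * basisPSII`, with fixed unit-area emission
#' basis spectra peaking at 740 nm (PSI) and 685/735 nm (PSII), multiplied
#' by a within-leaf reabsorption escape factor at the emission wavelength
#' (the interior transmission over half the elementary-plate absorption
#' depth: emitted photons originate throughout the leaf and must escape
#' it).  The escaping flux is split equally into backward (`Mb`) and
#' forward (`Mf`) hemispheres and entries with emission wavelength <=
#' excitation wavelength are zeroed (Stokes shift).
#'
#' @param params a [leafParams()] object.
#' @param fp a [fluorescenceParams()] object.
#' @param constants an [opticalConstants()] object covering 400-750 nm.
#' @param excitation excitation wavelength grid (nm), default 400-750.
#' @param emission emission wavelength grid (nm), default 640-850.
#' @return List with `excitation`, `emission`, and matrices `Mb`, `Mf`
#'   (rows = emission, columns = excitation; per-nm fractions).
#' @export
fluorescenceMatrices <- function(params, fp, constants,
                                 excitation = seq(400, 750, by = 1),
                                 emission = seq(640, 850, by = 1)) {
  stopifnot(inherits(fp, "fluorescenceParams"))
  spec <- plateRT(params, constants)
  absorbed <- 1 - spec$rho - spec$tau
  idx <- match(excitation, constants$wavelengths)
  if (anyNA(idx))
    stop("excitation grid must be a subset of the constants grid")
  absorbed <- pmax(absorbed[idx], 0)
  emis <- emission_shape(params, fp, constants, emission)
  M <- 0.5 * outer(emis, absorbed)       # emission x excitation
  stokes <- outer(emission, excitation, ">")
  M <- M * stokes
  list(excitation = excitation, emission = emission, Mb = M, Mf = M)
}
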