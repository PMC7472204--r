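#' Sun/view geometry and leaf inclination parameters
#'
#' @param theta_s sun zenith angle (deg, default 45).
#' @param theta_o view zenith angle (deg, default 0, nadir).
#' @param psi relative azimuth angle (deg, default 0).
#' @param lidf_a,lidf_b leaf inclination parameters (defaults -0.35, -0.15).
#' @return An object of class `geometry`.
#' @export
geometry <- function(theta_s = 45, theta_o = 0, psi = 0,
                     lidf_a = -0.35, lidf_b = -0.15) {
  if (theta_s < 0 || theta_s > 90 || theta_o < 0 || theta_o > 90)
    stop("zenith angles must lie in [0, 90] degrees")
  if (psi < 0 || psi > 360) stop("relative azimuth must lie in [0, 360]")
  if (abs(lidf_a) + abs(lidf_b) > 1 + 1e-12)
    stop("inadmissible LIDF parameters: |a| + |b| must be <= 1")
  structure(list(theta_s = theta_s, theta_o = theta_o, psi = psi,
                 lidf_a = lidf_a, lidf_b = lidf_b), class = "geometry")
}

# Volume-scattering geometry factors for one leaf inclination class:
# fractional interception for the sun (chi_s) and view (chi_o) directions
# and the bidirectional scattering geometry factors (frho, ftau).
volscatt <- function(tts, tto, psi, ttl) {
  rd <- pi / 180
  costs <- cos(rd * tts); costo <- cos(rd * tto)
  sints <- sin(rd * tts); sinto <- sin(rd * tto)
  cospsi <- cos(rd * psi); psir <- rd * psi
  costl <- cos(rd * ttl); sintl <- sin(rd * ttl)
  cs <- costl * costs; co <- costl * costo
  ss <- sintl * sints; so <- sintl * sinto

  cosbts <- 5
  if (abs(ss) > 1e-6) cosbts <- -cs / ss
  cosbto <- 5
  if (abs(so) > 1e-6) cosbto <- -co / so

  if (abs(cosbts) < 1) { bts <- acos(cosbts); ds <- ss
  } else { bts <- pi; ds <- cs }
  chi_s <- 2 / pi * ((bts - pi * 0.5) * cs + sin(bts) * ss)

  if (abs(cosbto) < 1) { bto <- acos(cosbto); doo <- so
  } else if (tto < 90) { bto <- pi; doo <- co
  } else { bto <- 0; doo <- -co }
  chi_o <- 2 / pi * ((bto - pi * 0.5) * co + sin(bto) * so)

  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psir <= btran1) { bt1 <- psir; bt2 <- btran1; bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psir <= btran2) { bt2 <- psir; bt3 <- btran2
    } else { bt2 <- btran2; bt3 <- psir }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- 0
  if (bt2 > 0) t2 <- sin(bt2) * (2 * ds * doo + ss * so * cos(bt1) * cos(bt3))
  denom <- 2 * pi^2
  frho <- max(((pi - bt2) * t1 + t2) / denom, 0)
  ftau <- max((-bt1 * t1 + t2) / denom, 0)
  c(chi_s = chi_s, chi_o = chi_o, frho = frho, ftau = ftau)
}

# Geometric (wavelength-independent) SAIL coefficient factors for a canopy
# of azimuthally uniform leaves with the given inclination distribution.
# All quantities are per unit leaf area index.
sail_geometry <- function(geom) {
  lidf <- lidfDistribution(geom$lidf_a, geom$lidf_b)
  angles <- attr(lidf, "angles")
  rd <- pi / 180
  cts <- cos(rd * geom$theta_s)
  cto <- cos(rd * geom$theta_o)
  ks <- ko <- bf <- sob <- sof <- 0
  for (i in seq_along(angles)) {
    v <- volscatt(geom$theta_s, geom$theta_o, geom$psi, angles[i])
    ks <- ks + v[["chi_s"]] / cts * lidf[i]
    ko <- ko + v[["chi_o"]] / cto * lidf[i]
    sob <- sob + v[["frho"]] * pi / (cts * cto) * lidf[i]
    sof <- sof + v[["ftau"]] * pi / (cts * cto) * lidf[i]
    bf <- bf + cos(rd * angles[i])^2 * lidf[i]
  }
  list(ks = ks, ko = ko,
       sdb = 0.5 * (ks + bf), sdf = 0.5 * (ks - bf),
       dob = 0.5 * (ko + bf), dof = 0.5 * (ko - bf),
       ddb = 0.5 * (1 + bf), ddf = 0.5 * (1 - bf),
       sob = sob, sof = sof)
}

#' Per-wavelength SAIL layer coefficients
#'
#' Combines the geometric factors with the leaf single-scattering spectra to
#' give, per unit LAI and per wavelength: direct-beam extinction `ks`, view
#' extinction `ko`, diffuse attenuation `att`, backward/forward diffuse
#' scattering `sigb`/`sigf`, direct-to-diffuse scattering `sb`/`sf`,
#' diffuse-to-view `vb`/`vf` and the bidirectional factor `w`.
#'
#' @param leaf a `leafSpectra` object from [plateRT()].
#' @param geom a [geometry()] object.
#' @param geo optional precomputed result of the internal geometric factor
#'   computation (reuse across wavelengths/scenes with the same geometry).
#' @return List of per-wavelength coefficient vectors plus scalars `ks`,
#'   `ko` and `m` (the diffuse eigenvalue `sqrt(att^2 - sigb^2)`).
#' @export
layerCoefficients <- function(leaf, geom, geo = NULL) {
  if (is.null(geo)) geo <- sail_geometry(geom)
  rho <- leaf$rho; tau <- leaf$tau
  sigb <- geo$ddb * rho + geo$ddf * tau
  sigf <- geo$ddf * rho + geo$ddb * tau
  att <- 1 - sigf
  m <- sqrt(pmax(att^2 - sigb^2, 0))
  list(ks = geo$ks, ko = geo$ko,
       att = att, sigb = sigb, sigf = sigf, m = m,
       sb = geo$sdb * rho + geo$sdf * tau,
       sf = geo$sdf * rho + geo$sdb * tau,
       vb = geo$dob * rho + geo$dof * tau,
       vf = geo$dof * rho + geo$dob * tau,
       w = geo$sob * rho + geo$sof * tau)
}
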