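#' Sample a spectrum at a nominal band wavelength
#'
#' Nearest-grid-point sampling (exact on a 1-nm grid); no sensor response
#' convolution.
#'
#' @param spectrum numeric spectrum, or a `spectralOutput` /
#'   `sifSpectrum` object (its TOC curve is used).
#' @param lambda requested wavelength (nm).
#' @param wavelengths grid (nm); taken from the object when omitted.
#' @return The spectrum value at the nearest grid wavelength.
#' @export
band <- function(spectrum, lambda, wavelengths = NULL) {
  if (inherits(spectrum, "spectralOutput")) {
    wavelengths <- spectrum$wavelengths
    spectrum <- spectrum$toc_reflectance
  } else if (inherits(spectrum, "sifSpectrum")) {
    wavelengths <- spectrum$wavelengths
    spectrum <- spectrum$toc_f
  }
  if (is.null(wavelengths)) stop("wavelength grid required")
  if (lambda < min(wavelengths) || lambda > max(wavelengths))
    stop("wavelength ", lambda, " nm is outside the grid range")
  spectrum[which.min(abs(wavelengths - lambda))]
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    warning("undefined ", name, ": zero denominator")
    return(NA_real_)
  }
  num / den
}

#' Vegetation index battery
#'
#' Computes the index set from a top-of-canopy reflectance spectrum:
#' NDVI = (R810-R685)/(R810+R685), CIgreen = R810/R560 - 1,
#' NDVIgreen = (R810-R560)/(R810+R560), WI = R900/R970,
#' WRVI (1450/1940 and 1600/820), NDWI = (R860-R1240)/(R860+R1240),
#' RVI = R810/R685, and RVIf = F685/F730 when a fluorescence spectrum is
#' supplied.
#'
#' @param spectrum reflectance spectrum (numeric vector or
#'   `spectralOutput`).
#' @param wavelengths grid (nm) when `spectrum` is a plain vector.
#' @param sif optional `sifSpectrum` for RVIf.
#' @return A one-row data frame of class `VIRecord` with columns `ndvi`,
#'   `rvi`, `ci_green`, `ndvi_green`, `wi`, `wrvi_1450_1940`,
#'   `wrvi_1600_820`, `ndwi`, `rvif`.
#' @export
computeVIs <- function(spectrum, wavelengths = NULL, sif = NULL) {
  if (inherits(spectrum, "spectralOutput")) {
    wavelengths <- spectrum$wavelengths
    spectrum <- spectrum$toc_reflectance
  }
  b <- function(l) band(spectrum, l, wavelengths)
  r810 <- b(810); r685 <- b(685); r560 <- b(560)
  rec <- data.frame(
    ndvi = safe_ratio(r810 - r685, r810 + r685, "NDVI"),
    rvi = safe_ratio(r810, r685, "RVI"),
    ci_green = safe_ratio(r810, r560, "CIgreen") - 1,
    ndvi_green = safe_ratio(r810 - r560, r810 + r560, "NDVIgreen"),
    wi = safe_ratio(b(900), b(970), "WI"),
    wrvi_1450_1940 = safe_ratio(b(1450), b(1940), "WRVI(1450,1940)"),
    wrvi_1600_820 = safe_ratio(b(1600), b(820), "WRVI(1600,820)"),
    ndwi = safe_ratio(b(860) - b(1240), b(860) + b(1240), "NDWI"),
    rvif = if (is.null(sif)) NA_real_ else rvif(sif))
  class(rec) <- c("VIRecord", class(rec))
  rec
}

#' First derivative of a spectrum
#'
#' Central differences in the interior, one-sided differences at the ends,
#' in per-nm units.
#'
#' @param spectrum numeric spectrum or a `spectralOutput` object.
#' @param wavelengths grid (nm) when `spectrum` is a plain vector.
#' @return Numeric derivative spectrum on the same grid.
#' @export
firstDerivative <- function(spectrum, wavelengths = NULL) {
  if (inherits(spectrum, "spectralOutput")) {
    wavelengths <- spectrum$wavelengths
    spectrum <- spectrum$toc_reflectance
  }
  n <- length(spectrum)
  if (n < 3) stop("spectrum must have at least 3 grid points")
  d <- numeric(n)
  d[1] <- (spectrum[2] - spectrum[1]) / (wavelengths[2] - wavelengths[1])
  d[n] <- (spectrum[n] - spectrum[n - 1]) /
    (wavelengths[n] - wavelengths[n - 1])
  d[2:(n - 1)] <- (spectrum[3:n] - spectrum[1:(n - 2)]) /
    (wavelengths[3:n] - wavelengths[1:(n - 2)])
  d
}
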