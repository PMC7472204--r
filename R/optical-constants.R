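#' Leaf optical constants
#'
#' Container for the wavelength grid, leaf interior refractive index and the
#' specific absorption coefficient spectra of the leaf constituents:
#' chlorophyll a+b (`k_cab`, per ug/cm2), carotenoids (`k_cca`, per ug/cm2),
#' equivalent water thickness (`k_cw`, per cm), dry matter (`k_cdm`, per
#' g/cm2) and senescent brown pigments (`k_cs`, per unit fraction).
#'
#' @param wavelengths numeric wavelength grid in nm (strictly increasing).
#' @param n refractive index spectrum (>= 1 everywhere).
#' @param k_cab,k_cca,k_cw,k_cdm,k_cs non-negative specific absorption
#'   coefficient spectra, each the same length as `wavelengths`.
#' @return An object of class `opticalConstants`: a list with the fields
#'   above.
#' @export
opticalConstants <- function(wavelengths, n, k_cab, k_cca, k_cw, k_cdm, k_cs) {
  wavelengths <- as.numeric(wavelengths)
  spectra <- list(n = n, k_cab = k_cab, k_cca = k_cca, k_cw = k_cw,
                  k_cdm = k_cdm, k_cs = k_cs)
  for (nm in names(spectra)) {
    if (length(spectra[[nm]]) != length(wavelengths))
      stop("spectrum '", nm, "' has length ", length(spectra[[nm]]),
           " but the wavelength grid has length ", length(wavelengths))
  }
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(n < 1)) stop("refractive index must be >= 1 everywhere")
  for (nm in setdiff(names(spectra), "n"))
    if (any(spectra[[nm]] < 0)) stop("'", nm, "' must be non-negative")
  structure(c(list(wavelengths = wavelengths), spectra),
            class = "opticalConstants")
}

#' @export
print.opticalConstants <- function(x, ...) {
  cat("Leaf optical constants:", length(x$wavelengths), "wavelengths,",
      min(x$wavelengths), "-", max(x$wavelengths), "nm\n")
  invisible(x)
}

#' Read leaf optical constants from CSV
#'
#' Expects a header `wavelength_nm,n,k_cab,k_cca,k_cw,k_cdm,k_cs`.  When
#' `grid` is supplied the table is linearly interpolated onto it.
#'
#' @param path path to the CSV file.
#' @param grid optional target wavelength grid (nm).
#' @return An [opticalConstants()] object.
#' @export
readConstants <- function(path, grid = NULL) {
  tab <- utils::read.csv(path)
  need <- c("wavelength_nm", "n", "k_cab", "k_cca", "k_cw", "k_cdm", "k_cs")
  if (!all(need %in% names(tab)))
    stop("constants file must have columns: ", paste(need, collapse = ", "))
  if (is.null(grid)) grid <- tab$wavelength_nm
  interp <- function(y) stats::approx(tab$wavelength_nm, y, xout = grid,
                                      rule = 2)$y
  opticalConstants(grid, interp(tab$n), pmax(interp(tab$k_cab), 0),
                   pmax(interp(tab$k_cca), 0), pmax(interp(tab$k_cw), 0),
                   pmax(interp(tab$k_cdm), 0), pmax(interp(tab$k_cs), 0))
}

#' Bundled leaf optical constants
#'
#' Loads the constants table shipped with the package, interpolated onto a
#' 1-nm grid (default 400-2400 nm).  The table is a synthetic reconstruction
#' of leaf-level spectroscopy: in-vivo chlorophyll absorption bands around
#' 430 and 660-680 nm decaying to zero through the red edge, carotenoid
#' absorption in the blue, pure-water absorption magnitudes with maxima near
#' 1450 and 1940 nm and the weak 970 nm band, dry-matter absorption rising
#' into the SWIR, and an exponentially decaying brown-pigment spectrum.  It
#' is not a redistribution of any published coefficient file.
#'
#' @param grid wavelength grid in nm.
#' @return An [opticalConstants()] object.
#' @export
defaultConstants <- function(grid = seq(400, 2400, by = 1)) {
  path <- system.file("extdata", "leaf_constants_synthetic.csv",
                      package = "mlcanopy", mustWork = TRUE)
  readConstants(path, grid = grid)
}

#' Smooth synthetic leaf optical constants
#'
#' Generates a minimal, fully synthetic constant set so that every
#' computation can run without any bundled file: Gaussian chlorophyll
#' absorption bands at 430 and 660 nm, water bands at 1450 and 1940 nm, a
#' flat dry-matter spectrum and a flat refractive index.  Intended for tests
#' and for exercising the machinery, not for reproducing leaf spectra.
#'
#' @param grid wavelength grid in nm.
#' @return An [opticalConstants()] object.
#' @export
syntheticConstants <- function(grid = seq(400, 2400, by = 1)) {
  g <- function(mu, s) exp(-0.5 * ((grid - mu) / s)^2)
  opticalConstants(
    wavelengths = grid,
    n = rep(1.45, length(grid)),
    k_cab = 0.08 * g(430, 30) + 0.08 * g(660, 25),
    k_cca = 0.06 * g(460, 25),
    k_cw = 25 * g(1450, 40) + 110 * g(1940, 50) + 0.4 * g(970, 30),
    k_cdm = rep(6, length(grid)),
    k_cs = 1.2 * exp(-(grid - 400) / 250))
}
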