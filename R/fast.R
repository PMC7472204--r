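#' Extended FAST design
#'
#' Design for the extended Fourier Amplitude Sensitivity Test: each factor
#' is driven in turn at the highest admissible frequency
#' `omega_max = floor((Ns - 1) / (2 * M))` while the complementary factors
#' share low frequencies `1..max(1, floor(omega_max / (2 * M)))` assigned
#' cyclically, giving `Ns * k` model runs in total.
#'
#' @param bounds data frame with columns `factor`, `lower`, `upper`
#'   (default: the nine layered canopy factors — LAI, Chla+b and Cw of the
#'   top, middle and lower layers).
#' @param M interference factor (default 4).
#' @param Ns samples per factor; odd and at least `4 * M^2 + 1`
#'   (default 65).
#' @param seed optional seed for random phase shifts; the default uses
#'   zero phases (fully deterministic).
#' @return An object of class `fastDesign`.
#' @export
fastDesign <- function(bounds = fast_bounds, M = 4, Ns = 65, seed = NULL) {
  stopifnot(all(c("factor", "lower", "upper") %in% names(bounds)))
  if (any(bounds$lower >= bounds$upper))
    stop("each factor needs lower < upper bounds")
  if (Ns %% 2 == 0) stop("Ns must be odd")
  if (Ns < 4 * M^2 + 1)
    stop("Ns must be at least 4*M^2 + 1 = ", 4 * M^2 + 1)
  k <- nrow(bounds)
  omega_max <- floor((Ns - 1) / (2 * M))
  # distinct complementary frequencies 1..n, the fewest that put at most
  # two factors on each (a quarter-period offset makes a shared-frequency
  # pair uncorrelated); kept below omega_max/2 so complement main effects
  # stay under the total-order cutoff
  n_comp_freq <- max(1, min(ceiling((k - 1) / 2), omega_max %/% 2))
  omega_comp <- seq_len(n_comp_freq)
  phase <- if (is.null(seed)) rep(0, k) else
    with_preserved_seed(seed, stats::runif(k, 0, 2 * pi))
  structure(list(factors = bounds$factor, bounds = bounds, M = M, Ns = Ns,
                 omega_max = omega_max, omega_comp = omega_comp,
                 phase = phase, seed = seed),
            class = "fastDesign")
}

#' @export
print.fastDesign <- function(x, ...) {
  cat(sprintf(
    "FAST design: %d factors x Ns = %d -> %d runs (M = %d, omega_max = %d)\n",
    length(x$factors), x$Ns, x$Ns * length(x$factors), x$M, x$omega_max))
  invisible(x)
}

#' Sample matrix of a FAST design
#'
#' The search curve maps a uniform grid `s` over (-pi, pi) to each factor's
#' range through `x = lower + (upper - lower) *
#' (0.5 + asin(sin(omega * s + phase)) / pi)`.
#'
#' @param design a [fastDesign()] object.
#' @return Numeric matrix with `Ns * k` rows (one block of `Ns` rows per
#'   driven factor) and one column per factor; attribute `driven` gives
#'   the driven factor index of each row.
#' @export
fastSample <- function(design) {
  stopifnot(inherits(design, "fastDesign"))
  k <- length(design$factors)
  Ns <- design$Ns
  s <- pi * (2 * seq_len(Ns) - 1 - Ns) / Ns
  X <- matrix(0, Ns * k, k, dimnames = list(NULL, design$factors))
  driven <- integer(Ns * k)
  for (i in seq_len(k)) {
    # complementary factors take distinct low frequencies 1..omega_comp,
    # cyclically; factors forced to share a frequency are offset by a
    # quarter period.  Triangle waves at distinct frequencies, or at the
    # same frequency a quarter period apart, are uncorrelated, so the
    # complementary set does not leak covariance into the variance
    # partition (up to two factors may share each frequency).
    omega <- rep(0, k)
    shift <- rep(0, k)
    omega[i] <- design$omega_max
    comp <- setdiff(seq_len(k), i)
    nf <- length(design$omega_comp)
    omega[comp] <- design$omega_comp[((seq_along(comp) - 1) %% nf) + 1]
    shift[comp] <- ((seq_along(comp) - 1) %/% nf) * pi / 2
    rows <- (i - 1) * Ns + seq_len(Ns)
    for (j in seq_len(k)) {
      g <- 0.5 + asin(sin(omega[j] * s + design$phase[j] + shift[j])) / pi
      x <- design$bounds$lower[j] +
        (design$bounds$upper[j] - design$bounds$lower[j]) * g
      X[rows, j] <- pmin(pmax(x, design$bounds$lower[j]),
                         design$bounds$upper[j])
    }
    driven[rows] <- i
  }
  attr(X, "driven") <- driven
  X
}

# Fourier spectrum of one driven-factor output block: power at harmonics
# p = 1 .. (Ns-1)/2 of the search-curve parameter.
fast_spectrum <- function(y, Ns) {
  s <- pi * (2 * seq_len(Ns) - 1 - Ns) / Ns
  pmax_h <- (Ns - 1) %/% 2
  p <- seq_len(pmax_h)
  A <- vapply(p, function(pp) sum(y * cos(pp * s)) / Ns, numeric(1))
  B <- vapply(p, function(pp) sum(y * sin(pp * s)) / Ns, numeric(1))
  A^2 + B^2
}

#' First-order FAST index from one output block
#'
#' Ratio of the spectral power at the driven frequency and its first `M`
#' harmonics to the total spectral power, clamped to `[0, 1]`.
#'
#' @param y outputs of one driven-factor block (length `Ns`).
#' @param design a [fastDesign()] object.
#' @return First-order sensitivity index.
#' @export
fastFirstOrder <- function(y, design) {
  spec <- fast_spectrum(y, design$Ns)
  D <- sum(spec)
  if (D <= .Machine$double.eps * max(abs(y), 1)^2) {
    warning("output has (numerically) zero variance; index set to 0")
    return(0)
  }
  harm <- design$omega_max * seq_len(design$M)
  harm <- harm[harm <= length(spec)]
  min(max(sum(spec[harm]) / D, 0), 1)
}

#' Total-order FAST index from one output block
#'
#' One minus the share of spectral power below `omega_max / 2` (the
#' variance attributable to the complementary factor set), clamped to
#' `[0, 1]`.
#'
#' @inheritParams fastFirstOrder
#' @return Total-order sensitivity index.
#' @export
fastTotalOrder <- function(y, design) {
  spec <- fast_spectrum(y, design$Ns)
  D <- sum(spec)
  if (D <= .Machine$double.eps * max(abs(y), 1)^2) {
    warning("output has (numerically) zero variance; index set to 0")
    return(0)
  }
  cutoff <- design$omega_max %/% 2
  min(max(1 - sum(spec[seq_len(cutoff)]) / D, 0), 1)
}

#' Run a FAST analysis
#'
#' Evaluates the model on every design row and assembles first- and
#' total-order indices per factor and output.
#'
#' @param design a [fastDesign()] object.
#' @param model function mapping a named parameter vector to a numeric
#'   vector of outputs (e.g. band reflectances); all rows must yield
#'   outputs of the same length.
#' @param output_names optional names for the model outputs.
#' @param resample number of random-phase search curves to average over
#'   (default 1: the single deterministic curve of `design`).  Averaging
#'   over several curves reduces the single-curve estimation error of the
#'   indices at the cost of `resample` times as many model runs.
#' @return An object of class `fastResult`: list with matrices `s1` and
#'   `st` (factors x outputs), the per-output total `variance`, the number
#'   of model runs `n_runs`, and the design.
#' @export
runFAST <- function(design, model, output_names = NULL, resample = 1) {
  if (resample > 1) {
    base_seed <- design$seed %||% 0
    parts <- lapply(seq_len(resample), function(r)
      runFAST(fastDesign(design$bounds, M = design$M, Ns = design$Ns,
                         seed = base_seed + r), model,
              output_names = output_names))
    out <- parts[[1]]
    out$s1 <- Reduce(`+`, lapply(parts, `[[`, "s1")) / resample
    out$st <- Reduce(`+`, lapply(parts, `[[`, "st")) / resample
    out$variance <- Reduce(`+`, lapply(parts, `[[`, "variance")) / resample
    out$n_runs <- sum(vapply(parts, `[[`, numeric(1), "n_runs"))
    out$design <- design
    return(out)
  }
  X <- fastSample(design)
  k <- length(design$factors)
  Ns <- design$Ns
  first <- model(X[1, ])
  n_out <- length(first)
  Y <- matrix(0, nrow(X), n_out)
  Y[1, ] <- first
  for (r in 2:nrow(X)) {
    out <- tryCatch(model(X[r, ]),
                    error = function(e)
                      stop("model failed on design row ", r, ": ",
                           conditionMessage(e)))
    Y[r, ] <- out
  }
  if (is.null(output_names)) output_names <- colnames(Y)
  if (is.null(output_names)) output_names <- paste0("y", seq_len(n_out))
  s1 <- matrix(0, k, n_out, dimnames = list(design$factors, output_names))
  st <- s1
  variance <- numeric(n_out)
  for (i in seq_len(k)) {
    rows <- (i - 1) * Ns + seq_len(Ns)
    for (j in seq_len(n_out)) {
      y <- Y[rows, j]
      s1[i, j] <- fastFirstOrder(y, design)
      st[i, j] <- fastTotalOrder(y, design)
      variance[j] <- variance[j] + stats::var(y) / k
    }
  }
  names(variance) <- output_names
  structure(list(s1 = s1, st = st, variance = variance,
                 n_runs = nrow(X), design = design),
            class = "fastResult")
}

#' @export
print.fastResult <- function(x, ...) {
  cat("FAST result (", x$n_runs, " runs)\nFirst-order indices:\n", sep = "")
  print(round(x$s1, 4))
  cat("Total-order indices:\n")
  print(round(x$st, 4))
  invisible(x)
}

#' Canopy band-reflectance model for sensitivity analysis
#'
#' Builds the model function used by [runFAST()]: a named 9-vector of
#' layered parameters (`lai_top`, `lai_mid`, `lai_low`, `cab_top`, ...,
#' `cw_low`) is turned into a three-layer scene (carotenoids at 25% of
#' Chla+b, other parameters standard) and simulated at the requested
#' bands only.
#'
#' @param bands wavelengths (nm) at which reflectance is reported
#'   (default 560, 685, 810).
#' @param constants an [opticalConstants()] object on a full grid; it is
#'   subset/interpolated to `bands`.
#' @return Function: named numeric vector -> named band reflectances.
#' @export
canopyBandModel <- function(bands = c(560, 685, 810),
                            constants = defaultConstants()) {
  cb <- readConstants_from(constants, bands)
  function(x) {
    layers <- lapply(c("top", "mid", "low"), function(pos)
      canopyLayer(x[[paste0("lai_", pos)]],
                  standard_leaf(Cab = x[[paste0("cab_", pos)]],
                                Cw = x[[paste0("cw_", pos)]])))
    out <- simulateCanopy(canopyScene(layers, geom = geometry()), cb)
    stats::setNames(out$toc_reflectance, paste0("R", bands))
  }
}

# interpolate an existing constants object onto a new grid
readConstants_from <- function(constants, grid) {
  interp <- function(y) stats::approx(constants$wavelengths, y,
                                      xout = grid, rule = 2)$y
  opticalConstants(grid, interp(constants$n),
                   pmax(interp(constants$k_cab), 0),
                   pmax(interp(constants$k_cca), 0),
                   pmax(interp(constants$k_cw), 0),
                   pmax(interp(constants$k_cdm), 0),
                   pmax(interp(constants$k_cs), 0))
}

#' Bounds of the nine layered sensitivity factors
#'
#' @return Data frame with `factor`, `lower`, `upper` for LAI, Chla+b and
#'   Cw of the top, middle and lower canopy layers.
#' @export
fastBounds <- function() fast_bounds
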