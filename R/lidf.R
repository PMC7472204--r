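#' Leaf inclination distribution over 13 angle classes
#'
#' Two-parameter leaf inclination distribution function: `a` controls the
#' mean inclination and `b` the bimodality, with admissibility
#' `|a| + |b| <= 1`.  Fractions are returned for the 13 standard inclination
#' classes (midpoints 5, 15, ..., 75, 81, 83, 85, 87, 89 degrees).
#'
#' @param a,b distribution parameters; defaults -0.35 and -0.15.
#' @return Numeric vector of 13 non-negative fractions summing to 1, with
#'   the class midpoint angles (deg) as an attribute `angles`.
#' @export
lidfDistribution <- function(a = -0.35, b = -0.15) {
  if (abs(a) + abs(b) > 1 + 1e-12)
    stop("inadmissible LIDF parameters: |a| + |b| must be <= 1")
  upper <- c(seq(10, 80, by = 10), seq(82, 90, by = 2))
  F <- vapply(upper, function(th) lidf_cum(a, b, th), numeric(1))
  F[length(F)] <- 1
  freq <- diff(c(0, F))
  freq <- pmax(freq, 0)
  freq <- freq / sum(freq)
  attr(freq, "angles") <- c(seq(5, 75, by = 10), seq(81, 89, by = 2))
  freq
}

# Cumulative inclination distribution at angle theta (deg): solves the
# fixed point x = p + a sin(x) + b sin(2x)/2 with p = 2 theta (rad), then
# F = (2 y + p) / pi.
lidf_cum <- function(a, b, theta) {
  rd <- pi / 180
  if (a > 1) return(1 - cos(rd * theta))
  eps <- 1e-9
  x <- 2 * rd * theta
  p <- x
  repeat {
    y <- a * sin(x) + 0.5 * b * sin(2 * x)
    dx <- 0.5 * (y - x + p)
    x <- x + dx
    if (abs(dx) < eps) break
  }
  (2 * y + p) / pi
}
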