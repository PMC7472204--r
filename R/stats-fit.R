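#' Relative deviation of a measured from a simulated value
#'
#' `Bias = (simulated - measured) / simulated`, the simulated value being
#' the reference.
#'
#' @param simulated reference value(s), non-zero.
#' @param measured measured value(s).
#' @return Signed relative deviation.
#' @export
biasError <- function(simulated, measured) {
  if (any(simulated == 0)) stop("bias undefined: simulated reference is 0")
  (simulated - measured) / simulated
}

#' Root mean square error between paired series
#'
#' @param simulated,measured equal-length numeric vectors.
#' @return `sqrt(mean((simulated - measured)^2))`.
#' @export
rmse <- function(simulated, measured) {
  if (length(simulated) != length(measured))
    stop("series lengths differ")
  if (length(simulated) < 1) stop("empty series")
  sqrt(mean((simulated - measured)^2))
}

#' Linear or logarithmic correlation fit
#'
#' Ordinary least squares of `y = a*x + b` (`model = "linear"`) or
#' `y = a*ln(x) + b` (`model = "log"`), with the coefficient of
#' determination `r2 = 1 - SSres/SStot`.
#'
#' @param x,y numeric vectors of equal length (n >= 3); `x > 0` for the
#'   log model.
#' @param model `"linear"` or `"log"`.
#' @return An object of class `fitReport`: list with `model`, `a`, `b`,
#'   `r2`.
#' @export
fitVI <- function(x, y, model = c("linear", "log")) {
  model <- match.arg(model)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (model == "log") {
    if (any(x <= 0)) stop("log model requires x > 0")
    x <- log(x)
  }
  if (stats::var(x) == 0) stop("degenerate fit: x has zero variance")
  if (stats::var(y) == 0) stop("r2 undefined: y has zero variance")
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(model = model,
                 a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]),
                 r2 = r2),
            class = "fitReport")
}

#' @export
print.fitReport <- function(x, ...) {
  form <- if (x$model == "log") "y = %.4g ln(x) + %.4g" else "y = %.4g x + %.4g"
  cat(sprintf(paste0(form, "   R^2 = %.4f\n"), x$a, x$b, x$r2))
  invisible(x)
}
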