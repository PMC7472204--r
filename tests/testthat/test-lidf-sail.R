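test_that("leaf inclination distribution is a proper distribution", {
  f <- lidfDistribution(-0.35, -0.15)
  expect_length(f, 13)
  expect_true(all(f >= 0))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # a grid of admissible parameter pairs
  for (a in c(-1, -0.5, 0, 0.5, 1)) {
    b <- 0.9 - abs(a)
    if (b < 0) b <- 0
    fr <- lidfDistribution(a, b)
    expect_true(all(fr >= -1e-12))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
  expect_error(lidfDistribution(0.8, 0.5), "inadmissible")
})

test_that("mean inclination matches CDF quadrature", {
  quad_mean <- function(a, b) {
    # mean = integral of (1 - F(theta)) over 0..90 on a fine grid
    th <- seq(0.05, 89.95, by = 0.1)
    Fv <- vapply(th, function(t) mlcanopy:::lidf_cum(a, b, t), numeric(1))
    sum((1 - Fv) * 0.1)
  }
  class_mean <- function(a, b) {
    f <- lidfDistribution(a, b)
    sum(f * attr(f, "angles"))
  }
  # default inclination model: midpoint binning error is small
  expect_lt(abs(class_mean(-0.35, -0.15) - quad_mean(-0.35, -0.15)), 0.5)
  # planophile: mass piles up in the first 10-degree class, whose true
  # conditional mean sits below the class midpoint, so the binned mean
  # carries ~2 degrees of discretization bias
  expect_lt(abs(class_mean(1, 0) - quad_mean(1, 0)), 2.5)
  # the binned fractions themselves match the fine CDF exactly
  f <- lidfDistribution(1, 0)
  bounds <- c(seq(10, 80, by = 10), seq(82, 90, by = 2))
  Fb <- vapply(bounds, function(t) mlcanopy:::lidf_cum(1, 0, t), numeric(1))
  expect_equal(unclass(f), diff(c(0, Fb)), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("SAIL layer coefficients behave in limiting cases", {
  g <- geometry()
  grid <- seq(400, 800, by = 100)
  nl <- length(grid)
  black <- structure(list(wavelengths = grid, rho = rep(0, nl),
                          tau = rep(0, nl)), class = "leafSpectra")
  cf <- layerCoefficients(black, g)
  expect_true(all(cf$sigb == 0) && all(cf$sb == 0) && all(cf$w == 0))
  expect_gt(cf$ks, 0)
  # conservative leaves: single-scattering albedo 1 per unit LAI
  cons <- structure(list(wavelengths = grid, rho = rep(0.6, nl),
                         tau = rep(0.4, nl)), class = "leafSpectra")
  cc <- layerCoefficients(cons, g)
  expect_equal(unique(round(cc$sigb + cc$sigf, 12)), 1)
  expect_equal(unique(round(cc$sb + cc$sf, 12)), round(cc$ks, 12))

  # horizontal-leaf limit: direct-beam extinction per unit LAI equals 1
  gh <- geometry(lidf_a = 1, lidf_b = 0)
  ch <- layerCoefficients(black, gh)
  # with the near-horizontal 13-class distribution, interception ~ 1
  expect_lt(abs(ch$ks - 1), 0.05)
})
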