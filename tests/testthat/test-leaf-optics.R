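test_that("total absorption is a linear mix scaled by 1/N", {
  grid <- c(500, 550, 600)
  cst <- opticalConstants(grid, n = rep(1.4, 3),
                          k_cab = c(0, 0.01, 0), k_cca = c(0, 0, 0),
                          k_cw = c(0, 0, 0), k_cdm = c(0, 0, 0),
                          k_cs = c(0, 0, 0))
  zero <- leafParams(N = 1.5, Cab = 0, Cca = 0, Cw = 0, Cdm = 0, Cs = 0)
  expect_equal(totalAbsorption(zero, cst), c(0, 0, 0))

  p <- leafParams(N = 1.5, Cab = 40, Cca = 0, Cw = 0, Cdm = 0, Cs = 0)
  k <- totalAbsorption(p, cst)
  expect_equal(k[2], 40 * 0.01 / 1.5, tolerance = 1e-10)
  expect_equal(round(k[2], 4), 0.2667)

  p2 <- leafParams(N = 1.5, Cab = 80, Cca = 0, Cw = 0, Cdm = 0, Cs = 0)
  expect_equal(totalAbsorption(p2, cst), 2 * k)

  # mismatched spectrum lengths are rejected at construction
  expect_error(opticalConstants(grid, n = rep(1.4, 2), k_cab = rep(0, 3),
                                k_cca = rep(0, 3), k_cw = rep(0, 3),
                                k_cdm = rep(0, 3), k_cs = rep(0, 3)),
               "length")
})

test_that("plate model conserves energy and respects limits", {
  cst <- syntheticConstants(seq(400, 2400, by = 20))
  # no absorption: rho + tau = 1 everywhere
  zero <- leafParams(N = 1.5, Cab = 0, Cca = 0, Cw = 0, Cdm = 0, Cs = 0)
  sp <- plateRT(zero, cst)
  expect_true(all(abs(sp$rho + sp$tau - 1) < 1e-9))
  # opaque limit: huge water content kills transmission in water bands
  wet <- leafParams(N = 1.5, Cab = 0, Cca = 0, Cw = 5, Cdm = 0, Cs = 0)
  spw <- plateRT(wet, cst)
  i1450 <- which.min(abs(cst$wavelengths - 1440))
  expect_lt(spw$tau[i1450], 1e-6)
  # invariants across parameter draws
  set.seed(3)
  for (r in 1:10) {
    p <- leafParams(N = runif(1, 1, 3), Cab = runif(1, 0, 100),
                    Cca = runif(1, 0, 30), Cw = runif(1, 0, 0.05),
                    Cdm = runif(1, 0, 0.02), Cs = runif(1, 0, 1))
    s <- plateRT(p, cst)
    expect_true(all(s$rho >= 0 & s$tau >= 0 & s$rho + s$tau <= 1 + 1e-12))
  }
  expect_error(plateRT(leafParams(N = 0.5), cst), "N")
})

test_that("increasing an absorber content strictly decreases transmittance", {
  cst <- defaultConstants(seq(400, 2400, by = 50))
  base <- plateRT(leafParams(Cab = 20), cst)
  more <- plateRT(leafParams(Cab = 60), cst)
  sel <- cst$k_cab > 1e-4
  expect_true(all(more$tau[sel] < base$tau[sel]))
  basew <- plateRT(leafParams(Cw = 0.005), cst)
  morew <- plateRT(leafParams(Cw = 0.04), cst)
  selw <- cst$k_cw > 1e-3
  expect_true(all(morew$tau[selw] < basew$tau[selw]))
})

test_that("plate model agrees with quadrature/bounce-series oracle", {
  grid <- seq(400, 2400, by = 200)
  set.seed(11)
  for (r in 1:10) {
    k <- runif(length(grid), 0, 2)
    n <- runif(1, 1.3, 1.6)
    N <- sample(1:3, 1)
    cst <- opticalConstants(grid, rep(n, length(grid)),
                            k_cab = k, k_cca = 0 * k, k_cw = 0 * k,
                            k_cdm = 0 * k, k_cs = 0 * k)
    p <- leafParams(N = N, Cab = 1, Cca = 0, Cw = 0, Cdm = 0, Cs = 0)
    got <- plateRT(p, cst)
    want <- oracle_plate_stack(k * 1 / N, rep(n, length(grid)), N)
    expect_lt(max(abs(got$rho - want$rho)), 1e-4)
    expect_lt(max(abs(got$tau - want$tau)), 1e-4)
  }
})

test_that("fluorescence matrices scale correctly and respect Stokes shift", {
  cst <- syntheticConstants(seq(400, 850, by = 5))
  exc <- seq(400, 750, by = 5)
  emi <- seq(640, 850, by = 5)
  p <- leafParams()
  off <- fluorescenceMatrices(p, fluorescenceParams(0, 0), cst,
                              excitation = exc, emission = emi)
  expect_true(all(off$Mb == 0) && all(off$Mf == 0))

  m1 <- fluorescenceMatrices(p, fluorescenceParams(0.004, 0.02), cst,
                             excitation = exc, emission = emi)
  m2 <- fluorescenceMatrices(p, fluorescenceParams(0.008, 0.04), cst,
                             excitation = exc, emission = emi)
  expect_equal(m2$Mb, 2 * m1$Mb, tolerance = 1e-12)
  expect_true(all(m1$Mb >= 0))
  # Stokes shift: emission at or below excitation is zero
  viol <- outer(emi, exc, "<=") & m1$Mb != 0
  expect_false(any(viol))
  # zero absorption at an excitation wavelength zeroes that column
  czero <- opticalConstants(cst$wavelengths, rep(1.0, length(cst$wavelengths)),
                            0 * cst$k_cab, 0 * cst$k_cca, 0 * cst$k_cw,
                            0 * cst$k_cdm, 0 * cst$k_cs)
  mz <- fluorescenceMatrices(leafParams(Cab = 0, Cca = 0, Cw = 0, Cdm = 0,
                                        Cs = 0),
                             fluorescenceParams(), czero,
                             excitation = exc, emission = emi)
  expect_true(all(mz$Mb == 0))
})
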