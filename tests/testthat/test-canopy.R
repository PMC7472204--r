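cstc <- coarse_constants()

test_that("identity layer and bare-soil limits are exact", {
  leaf <- leafParams()
  sc0 <- canopyScene(canopyLayer(0, leaf))
  out0 <- simulateCanopy(sc0, cstc)
  expect_equal(out0$toc_reflectance, out0$soil_reflectance)

  # a zero-LAI layer leaves the stack operator unchanged
  lv <- plateRT(leaf, cstc)
  cf <- layerCoefficients(lv, geometry())
  op0 <- mlcanopy:::layer_operator(cf, 0)
  below <- mlcanopy:::soil_operator(rep(0.3, length(cstc$wavelengths)))
  comb <- addLayer(op0, below)
  expect_equal(comb$rsd, below$rsd)
  expect_equal(comb$rdd, below$rdd)

  # black soil + black (non-scattering) leaves: zero TOC reflectance
  nl <- length(cstc$wavelengths)
  blackleaf <- structure(list(wavelengths = cstc$wavelengths,
                              rho = rep(0, nl), tau = rep(0, nl)),
                         class = "leafSpectra")
  bop <- mlcanopy:::layer_operator(layerCoefficients(blackleaf, geometry()), 3)
  bcomb <- addLayer(bop, mlcanopy:::soil_operator(rep(0, nl)))
  expect_lt(max(abs(bcomb$rsd)), 1e-12)
  expect_lt(max(abs(bcomb$rdd)), 1e-12)
})

test_that("homogeneous split invariance holds for K in {2,3,5}", {
  leaf <- leafParams()
  one <- simulateCanopy(canopyScene(canopyLayer(3, leaf)), cstc)
  for (K in c(2, 3, 5)) {
    lay <- replicate(K, canopyLayer(3 / K, leaf), simplify = FALSE)
    outK <- simulateCanopy(canopyScene(lay), cstc)
    expect_lt(max(abs(outK$toc_reflectance - one$toc_reflectance)), 1e-9)
  }
})

test_that("conservative scattering over bright soil gives unit albedo", {
  grid <- seq(400, 700, by = 50)
  nl <- length(grid)
  cst <- opticalConstants(grid, rep(1.0, nl), rep(0, nl), rep(0, nl),
                          rep(0, nl), rep(0, nl), rep(0, nl))
  # n = 1 and zero absorption make rho + tau = 1 leaves
  leaf <- leafParams(Cab = 0, Cca = 0, Cw = 0, Cdm = 0, Cs = 0)
  sp <- plateRT(leaf, cst)
  expect_true(all(abs(sp$rho + sp$tau - 1) < 1e-12))
  sc <- canopyScene(list(canopyLayer(2, leaf), canopyLayer(1.5, leaf)),
                    soil = 1)
  out <- simulateCanopy(sc, cst)
  expect_true(all(abs(out$toc_reflectance - 1) < 1e-6))
})

test_that("heterogeneous scenes match the fine-discretization oracle", {
  grid <- seq(450, 2350, by = 250)
  cst <- defaultConstants(grid)
  geo <- geometry()
  set.seed(21)
  for (r in 1:10) {
    lais <- c(runif(1, 0.15, 1.2), runif(1, 0.25, 2), runif(1, 0.1, 0.8))
    cabs <- c(runif(1, 7.5, 82.5), runif(1, 10, 110), runif(1, 5, 55))
    cws <- c(runif(1, 0.001, 0.07), runif(1, 0.0012, 0.07),
             runif(1, 5e-04, 0.04))
    layers <- lapply(1:3, function(j)
      canopyLayer(lais[j], leafParams(Cab = cabs[j], Cca = 0.25 * cabs[j],
                                      Cw = cws[j])))
    sc <- canopyScene(layers)
    out <- simulateCanopy(sc, cst)
    soil <- out$soil_reflectance
    coefs <- lapply(layers, function(l)
      layerCoefficients(plateRT(l$leaf, cst), geo))
    want <- oracle_canopy_reflectance(coefs, lais, soil)
    expect_lt(max(abs(out$toc_reflectance - want)), 1e-3)
  }
})

test_that("layer order matters for heterogeneous canopies", {
  dense_top <- canopyScene(list(
    canopyLayer(2, leafParams(Cab = 80, Cca = 20)),
    canopyLayer(0.5, leafParams(Cab = 20, Cca = 5))))
  dense_bottom <- canopyScene(list(
    canopyLayer(0.5, leafParams(Cab = 20, Cca = 5)),
    canopyLayer(2, leafParams(Cab = 80, Cca = 20))))
  a <- simulateCanopy(dense_top, cstc)
  b <- simulateCanopy(dense_bottom, cstc)
  expect_gt(max(abs(a$toc_reflectance - b$toc_reflectance)), 1e-3)
})

test_that("all reflectances stay within [0,1] across random scenes", {
  set.seed(5)
  for (r in 1:5) {
    n <- sample(1:5, 1)
    layers <- replicate(n, canopyLayer(runif(1, 0, 2),
                                       leafParams(Cab = runif(1, 0, 100),
                                                  Cca = runif(1, 0, 25),
                                                  Cw = runif(1, 0, 0.05))),
                        simplify = FALSE)
    out <- simulateCanopy(canopyScene(layers), cstc)
    expect_true(all(out$toc_reflectance >= 0 & out$toc_reflectance <= 1))
    expect_true(all(out$layer_top_reflectance >= 0 &
                      out$layer_top_reflectance <= 1))
  }
})

test_that("peeling is self-consistent and closes the energy budget", {
  sc <- threeLayerStandard()
  out <- simulateCanopy(sc, cstc)
  ops <- out$operators
  sub <- out$substacks
  for (i in seq_along(ops)) {
    op <- ops[[i]]
    # re-propagating boundary fluxes through layer i reproduces the next
    # boundary
    es_next <- op$tss * out$flux_direct[i, ]
    ed_next <- op$tsd * out$flux_direct[i, ] + op$tdd * out$flux_down[i, ] +
      op$rdd * out$flux_up[i + 1, ]
    expect_lt(max(abs(es_next - out$flux_direct[i + 1, ])), 1e-10)
    expect_lt(max(abs(ed_next - out$flux_down[i + 1, ])), 1e-10)
  }
  # downward total flux decreases with depth in an absorbing canopy
  down <- out$flux_direct + out$flux_down
  expect_true(all(diff(down[, 30]) <= 1e-12))
  # incident = reflected + absorbed by layers + absorbed by soil
  total <- out$toc_reflectance + colSums(out$absorbed) + out$soil_absorbed
  expect_true(all(abs(total - 1) < 1e-6))
})

test_that("LAI drives reflectance down in the red and up in the NIR", {
  lai_vals <- c(0.5, 1, 2, 3, 4, 5, 6)
  sw <- sweepScenes("LAI", lai_vals)
  r685 <- r810 <- numeric(length(lai_vals))
  for (i in seq_along(sw$scenes)) {
    out <- simulateCanopy(sw$scenes[[i]], cstc)
    r685[i] <- band(out, 685)
    r810[i] <- band(out, 810)
  }
  expect_true(all(diff(r685) < 0))
  expect_true(all(diff(r810) > 0))
})
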