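test_that("standard scenes carry the standard parameter values", {
  sc <- standardScene()
  expect_length(sc$layers, 1)
  expect_equal(sc$layers[[1]]$leaf$Cab, 40)
  expect_equal(sc$layers[[1]]$leaf$Cca, 10)
  expect_equal(sc$layers[[1]]$lai, 3)
  expect_equal(sc$geometry$theta_s, 45)
  expect_equal(sc$geometry$lidf_a, -0.35)

  out <- simulateCanopy(sc, coarse_constants())
  expect_true(all(out$toc_reflectance >= 0 & out$toc_reflectance <= 1))
})

test_that("three-layer standard profiles follow the layered design", {
  sc <- threeLayerStandard()
  expect_length(sc$layers, 3)
  lais <- vapply(sc$layers, `[[`, numeric(1), "lai")
  cabs <- vapply(sc$layers, function(l) l$leaf$Cab, numeric(1))
  cws <- vapply(sc$layers, function(l) l$leaf$Cw, numeric(1))
  expect_equal(lais, c(0.75, 1.25, 0.05))
  expect_equal(cabs, c(80, 60, 40))
  expect_equal(cws, c(0.02, 0.021, 0.01))
  expect_equal(sum(lais), 2.05)
  # carotenoids at 25% of chlorophyll
  expect_equal(vapply(sc$layers, function(l) l$leaf$Cca, numeric(1)),
               0.25 * cabs)
  # middle layer has the highest LAI
  expect_equal(which.max(lais), 2L)
})

test_that("layer-count scenarios follow the per-layer design table", {
  set <- layerCountScenarios()
  expect_length(set$scenes, 7)
  s1 <- set$scenes[[1]]
  expect_length(s1$layers, 1)
  expect_equal(s1$layers[[1]]$lai, 4.78)
  expect_equal(s1$layers[[1]]$leaf$Cab, 70)
  s3 <- set$scenes[[3]]
  expect_equal(vapply(s3$layers, `[[`, numeric(1), "lai"), c(1.5, 2, 1.28))
  expect_equal(unique(vapply(s3$layers, function(l) l$leaf$Cab,
                             numeric(1))), 40)
  expect_equal(sum(vapply(s3$layers, `[[`, numeric(1), "lai")), 4.78)
  # water content fixed at 0.009 cm in this design
  expect_true(all(vapply(set$scenes, function(s) s$layers[[1]]$leaf$Cw,
                         numeric(1)) == 0.009))
})

test_that("verification scenes respect bounds, means and ordering", {
  set <- verificationScenes(n = 21, seed = 99)
  expect_length(set$scenes, 21)
  vb <- mlcanopy:::verification_bounds
  for (f in vb$factor) {
    v <- set$metadata[[f]]
    row <- vb[vb$factor == f, ]
    expect_true(all(v >= row$min & v <= row$max))
    expect_lt(abs(mean(v) - row$mean), 0.15 * row$mean)
  }
  # ordered dense to sparse
  expect_true(all(diff(set$metadata$total_lai) <= 0))
  # seeded reproducibility
  again <- verificationScenes(n = 21, seed = 99)
  expect_identical(set$metadata, again$metadata)
  other <- verificationScenes(n = 21, seed = 100)
  expect_false(identical(set$metadata, other$metadata))
  expect_error(verificationScenes(n = 21), "seed")
})

test_that("sweeps vary one parameter and hold the rest standard", {
  vals <- c(5, 10, 20, 30, 40, 50, 70)
  sw <- sweepScenes("Cab", vals)
  expect_length(sw$scenes, 7)
  cabs <- vapply(sw$scenes, function(s) s$layers[[1]]$leaf$Cab, numeric(1))
  expect_equal(cabs, vals)
  ccas <- vapply(sw$scenes, function(s) s$layers[[1]]$leaf$Cca, numeric(1))
  expect_equal(ccas, 0.25 * vals)
  lais <- vapply(sw$scenes, function(s) s$layers[[1]]$lai, numeric(1))
  expect_true(all(lais == 3))
  cws <- vapply(sw$scenes, function(s) s$layers[[1]]$leaf$Cw, numeric(1))
  expect_true(all(cws == 0.015))

  expect_length(sweepScenes("LAI", numeric(0))$scenes, 0)
  expect_warning(sweepScenes("Cw", 0.2), "guidance range")

  lay <- sweepScenes("LAI", c(1, 2.05, 4), mode = "layered")
  tot <- vapply(lay$scenes, function(s)
    sum(vapply(s$layers, `[[`, numeric(1), "lai")), numeric(1))
  expect_equal(tot, c(1, 2.05, 4), tolerance = 1e-12)
})

test_that("scenes round-trip through YAML unchanged", {
  path <- withr::local_tempfile(fileext = ".yaml")
  sc <- threeLayerStandard()
  writeScene(sc, path)
  back <- readScene(path)
  expect_equal(back$layers, sc$layers, tolerance = 1e-9)
  expect_equal(back$geometry, sc$geometry, tolerance = 1e-9)
  expect_equal(back$soil$reflectance, sc$soil$reflectance, tolerance = 1e-9)
})
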