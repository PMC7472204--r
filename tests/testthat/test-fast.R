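test_that("the design produces Ns*k bounded, reproducible samples", {
  d <- fastDesign()
  expect_equal(d$Ns * length(d$factors), 585)
  X <- fastSample(d)
  expect_equal(nrow(X), 585)
  expect_equal(ncol(X), 9)
  b <- fastBounds()
  for (j in seq_len(ncol(X))) {
    expect_true(all(X[, j] >= b$lower[j] & X[, j] <= b$upper[j]))
  }
  expect_true(all(X[, "lai_top"] >= 1 & X[, "lai_top"] <= 6))
  # deterministic by default and under a fixed seed
  expect_identical(X, fastSample(fastDesign()))
  expect_identical(fastSample(fastDesign(seed = 4)),
                   fastSample(fastDesign(seed = 4)))
  expect_false(identical(fastSample(fastDesign(seed = 4)),
                         fastSample(fastDesign(seed = 5))))
  expect_error(fastDesign(Ns = 64), "odd")
  expect_error(fastDesign(Ns = 33), "4\\*M\\^2")
  bad <- fastBounds(); bad$lower[1] <- bad$upper[1]
  expect_error(fastDesign(bad), "lower < upper")
})

test_that("index estimators handle pure dependence and degeneracy", {
  b <- data.frame(factor = c("x1", "x2", "x3"), lower = 0, upper = 1)
  d <- fastDesign(b)
  r <- runFAST(d, function(x) x[["x2"]]^2)
  expect_gt(r$s1["x2", 1], 0.95)
  expect_lt(r$s1["x1", 1], 0.05)
  expect_true(all(r$st >= r$s1 - 0.02))

  expect_warning(fastFirstOrder(rep(1, d$Ns), d), "zero variance")
  expect_warning(fastTotalOrder(rep(1, d$Ns), d), "zero variance")
  rc <- suppressWarnings(runFAST(d, function(x) 1))
  expect_true(all(rc$s1 == 0) && all(rc$st == 0))
})

test_that("linear-model indices match the analytic variance decomposition", {
  for (k in c(2, 4, 9)) {
    b <- data.frame(factor = paste0("x", seq_len(k)), lower = 0, upper = 1)
    a <- seq_len(k)
    r <- runFAST(fastDesign(b), function(x) sum(a * unlist(x)))
    analytic <- a^2 / sum(a^2)
    expect_lt(max(abs(r$s1[, 1] - analytic)), 0.05)
    expect_lt(max(abs(r$st[, 1] - analytic)), 0.05)
    # additive model: no interactions, st ~ s1
    expect_lt(max(abs(r$st[, 1] - r$s1[, 1])), 0.05)
  }
})

test_that("interaction-only models inflate the total-order index", {
  b <- data.frame(factor = c("x1", "x2"), lower = -1, upper = 1)
  r <- runFAST(fastDesign(b), function(x) x[[1]] * x[[2]])
  expect_lt(r$s1["x1", 1], 0.05)
  expect_gt(r$st["x1", 1], 0.5)
  expect_gt(r$st["x1", 1], r$s1["x1", 1])
})

test_that("Ishigami indices match the analytic decomposition", {
  b <- data.frame(factor = c("x1", "x2", "x3"), lower = -pi, upper = pi)
  r <- runFAST(fastDesign(b), ishigami, resample = 16)
  expect_lt(max(abs(r$s1[, 1] - ishigami_analytic$s1)), 0.05)
  # x3 acts only through its interaction with x1
  expect_lt(r$s1["x3", 1], 0.05)
  expect_gt(r$st["x3", 1], 0.2)
  expect_lt(abs(r$st["x1", 1] - ishigami_analytic$st[1]), 0.05)
  expect_lt(abs(r$st["x3", 1] - ishigami_analytic$st[3]), 0.05)
})

test_that("FAST agrees with a brute-force Sobol oracle on a linear model", {
  k <- 5
  b <- data.frame(factor = paste0("x", seq_len(k)), lower = 0, upper = 2)
  a <- c(3, 1, 4, 1, 5)
  model <- function(x) sum(a * unlist(x))
  r <- runFAST(fastDesign(b), model)
  mc <- oracle_sobol(function(row) sum(a * row), rep(0, k), rep(2, k),
                     n = 3000)
  expect_lt(max(abs(r$s1[, 1] - mc$s1)), 0.03)
  expect_lt(max(abs(r$st[, 1] - mc$st)), 0.03)
})

test_that("the canopy band model maps layered parameters to reflectances", {
  model <- canopyBandModel(constants = coarse_constants())
  x <- stats::setNames(c(1.5, 1.2, 0.5, 50, 40, 30, 0.01, 0.008, 0.005),
                       fastBounds()$factor)
  y <- model(as.list(x))
  expect_named(y, c("R560", "R685", "R810"))
  expect_true(all(y >= 0 & y <= 1))
  # more top-layer chlorophyll darkens the visible bands
  x2 <- x; x2[["cab_top"]] <- 80
  y2 <- model(as.list(x2))
  expect_lt(y2[["R560"]], y[["R560"]])
})
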