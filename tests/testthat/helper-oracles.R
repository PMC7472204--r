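# Independent oracles used by the tests.  These deliberately avoid the
# package's analytic solution paths: quadrature instead of closed forms,
# explicit series summation instead of the adding algebra, fine
# discretization instead of exponential layer solutions.

# hemispherical transmission of an absorbing slab by Gauss-type quadrature
# over exit angles (checks the exponential-integral closed form)
oracle_slab_transmission <- function(k, n_quad = 4000) {
  mu <- (seq_len(n_quad) - 0.5) / n_quad
  vapply(k, function(kk) sum(2 * mu * exp(-kk / mu)) / n_quad, numeric(1))
}

# one-plate leaf by explicit multiple-reflection bounce summation
oracle_plate <- function(k, n, alpha = 40, n_bounce = 400) {
  tau <- oracle_slab_transmission(k)
  talf <- mlcanopy:::tav(alpha, n)
  t12 <- mlcanopy:::tav(90, n)
  t21 <- t12 / n^2
  r21 <- 1 - t21
  # radiation enters through the top interface, then bounces between the
  # internal faces of the two interfaces with one slab pass per leg
  rho <- 1 - talf
  tau_out <- 0
  down <- talf * tau                 # at bottom interface, going down
  for (b in seq_len(n_bounce)) {
    tau_out <- tau_out + down * t21
    up <- down * r21 * tau           # reflected up, back at top interface
    rho <- rho + up * t21
    down <- up * r21 * tau
  }
  list(rho = rho, tau = tau_out)
}

# N-plate stack (integer N) built by adding internal plates one at a time,
# instead of the Stokes closed form.  The top plate sees a 40-degree cone;
# its underside reflectance/transmittance for radiation returning from the
# substack are the internal (diffuse) one-plate values.
oracle_plate_stack <- function(k, n, N, alpha = 40) {
  stopifnot(abs(N - round(N)) < 1e-12, N >= 1)
  top <- oracle_plate(k, n, alpha = alpha)
  inner <- oracle_plate(k, n, alpha = 90)
  if (N == 1) return(top)
  Rs <- inner$rho; Ts <- inner$tau       # substack of internal plates
  for (i in seq_len(N - 2)) {
    cl <- 1 / (1 - Rs * inner$rho)
    Ts_new <- Ts * inner$tau * cl
    Rs <- Rs + Ts^2 * inner$rho * cl
    Ts <- Ts_new
  }
  cl <- 1 / (1 - Rs * inner$rho)
  list(rho = top$rho + top$tau * Rs * inner$tau * cl,
       tau = top$tau * Ts * cl)
}

# fine-discretization two-stream oracle for a canopy layer stack over soil:
# first-order thin-layer operators composed by explicit interface
# bookkeeping, 2^doublings sublayers per layer
oracle_canopy_reflectance <- function(coefs, lais, soil, doublings = 15) {
  combine <- function(a, b) {   # a above b
    cl <- 1 / (1 - a$rdd * b$rdd)
    d <- (a$tsd + a$rdd * b$rsd * a$tss) * cl
    list(tss = a$tss * b$tss,
         tsd = b$tsd * a$tss + b$tdd * d,
         tdd = b$tdd * a$tdd * cl,
         rsd = a$rsd + a$tdd * (b$rsd * a$tss + b$rdd * d),
         rdd = a$rdd + a$tdd^2 * b$rdd * cl)
  }
  stack <- list(tss = 0 * soil, tsd = 0 * soil, tdd = 0 * soil,
                rsd = soil, rdd = soil)
  for (i in rev(seq_along(lais))) {
    cf <- coefs[[i]]
    dL <- lais[i] / 2^doublings
    thin <- list(tss = exp(-cf$ks * dL) + 0 * cf$att,
                 tsd = cf$sf * dL, tdd = 1 - cf$att * dL,
                 rsd = cf$sb * dL, rdd = cf$sigb * dL)
    lay <- thin
    for (d in seq_len(doublings)) lay <- combine(lay, lay)
    stack <- combine(lay, stack)
  }
  stack$rsd
}

# brute-force pick-freeze Monte-Carlo Sobol indices (Jansen estimators)
oracle_sobol <- function(model, lower, upper, n = 4000, seed = 7) {
  k <- length(lower)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draw <- function() sapply(seq_len(k), function(j)
    stats::runif(n, lower[j], upper[j]))
  A <- draw(); B <- draw()
  ya <- apply(A, 1, model); yb <- apply(B, 1, model)
  V <- stats::var(c(ya, yb))
  s1 <- st <- numeric(k)
  for (j in seq_len(k)) {
    AB <- A; AB[, j] <- B[, j]
    yab <- apply(AB, 1, model)
    s1[j] <- (V - 0.5 * mean((yb - yab)^2)) / V
    st[j] <- 0.5 * mean((ya - yab)^2) / V
  }
  list(s1 = s1, st = st)
}

# analytic Ishigami variance decomposition (a = 7, b = 0.1)
ishigami <- function(x) sin(x[[1]]) + 7 * sin(x[[2]])^2 +
  0.1 * x[[3]]^4 * sin(x[[1]])
ishigami_analytic <- local({
  a <- 7; b <- 0.1
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(s1 = c(V1, V2, 0) / V,
       st = c(V1 + V13, V2, V13) / V)
})

# small wavelength grids for fast canopy tests
coarse_grid <- seq(400, 2400, by = 10)
coarse_constants <- function() defaultConstants(coarse_grid)
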