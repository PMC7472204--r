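# Generator (run from the package root) for inst/extdata/leaf_constants_synthetic.csv
# Realistic leaf optical constants on a 5-nm grid (interpolated to 1 nm at load).
wl <- seq(400, 2400, by = 5)
G <- function(mu, s) exp(-0.5 * ((wl - mu) / s)^2)
sigmoid <- function(x) 1 / (1 + exp(-x))

# refractive index: ~1.52 at 400 nm declining to ~1.40 in the SWIR
n <- 1.39 + 0.13 * exp(-(wl - 400) / 700)

# chlorophyll a+b specific absorption (per ug/cm2): Soret + red bands,
# green trough, red-edge decay to zero by ~750 nm
k_cab <- (0.10 * G(432, 28) + 0.05 * G(470, 28) + 0.016 * G(585, 55) +
          0.022 * G(628, 22) + 0.078 * G(663, 14) + 0.040 * G(680, 12) +
          0.006 * G(700, 12)) * sigmoid((745 - wl) / 8)

# carotenoids (per ug/cm2): blue only
k_cca <- (0.09 * G(452, 26) + 0.06 * G(488, 18)) * sigmoid((540 - wl) / 10)

# water (per cm of equivalent water thickness): pure-water absorption anchors
# (Hale-Querry-style magnitudes), log-spline interpolated
anchor_wl <- c(400, 450, 500, 550, 600, 650, 700, 750, 800, 850, 900, 925,
               950, 975, 1000, 1050, 1100, 1150, 1200, 1250, 1300, 1350,
               1400, 1450, 1500, 1550, 1600, 1650, 1700, 1750, 1800, 1850,
               1900, 1940, 1980, 2000, 2050, 2100, 2150, 2200, 2250, 2300,
               2350, 2400)
anchor_k <- c(0.00058, 0.00029, 0.00025, 0.00045, 0.0023, 0.0034, 0.0060,
              0.0262, 0.0196, 0.0433, 0.0679, 0.144, 0.29, 0.50, 0.36,
              0.119, 0.178, 0.93, 1.04, 0.84, 1.18, 2.9, 11.0, 28.9, 19.5,
              10.0, 6.7, 5.9, 6.0, 6.5, 7.9, 11.0, 65.0, 125.0, 95.0, 69.1,
              39.0, 22.0, 18.0, 28.0, 36.0, 45.0, 52.0, 50.0)
k_cw <- exp(spline(anchor_wl, log(anchor_k), xout = wl)$y)

# dry matter (per g/cm2): nearly transparent in the VIS/NIR, rising into
# the SWIR with cellulose/lignin-style features
k_cdm <- 0.8 + 28 * sigmoid((wl - 1500) / 220) + 10 * G(1720, 60) +
  28 * G(2130, 90) + 25 * G(2310, 70)

# senescent brown pigments (per unit fraction): exponential decay from
# 400 nm, gone by the NIR plateau
k_cs <- 1.3 * exp(-(wl - 400) / 250) * sigmoid((800 - wl) / 30)

tab <- data.frame(wavelength_nm = wl,
                  n = signif(n, 6),
                  k_cab = signif(pmax(k_cab, 0), 5),
                  k_cca = signif(pmax(k_cca, 0), 5),
                  k_cw = signif(pmax(k_cw, 0), 5),
                  k_cdm = signif(pmax(k_cdm, 0), 5),
                  k_cs = signif(pmax(k_cs, 0), 5))
write.csv(tab, "inst/extdata/leaf_constants_synthetic.csv",
          row.names = FALSE, quote = FALSE)
cat("rows:", nrow(tab), " size:",
    file.size("inst/extdata/leaf_constants_synthetic.csv"), "bytes\n")
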