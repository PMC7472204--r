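Package: mlcanopy
Title: Multilayer Canopy Radiative Transfer, Fluorescence and Global
    Sensitivity Analysis for Vertically Heterogeneous Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates top-of-canopy reflectance (400-2400 nm) and
    sun-induced chlorophyll fluorescence (640-850 nm) of vertically
    heterogeneous crop canopies such as winter wheat.  Leaf optical
    properties come from a generalized plate model with a simplified
    fluorescence excitation-emission matrix; the canopy is stratified into
    1-60 uniform layers whose SAIL-type four-stream operators are combined
    by a bottom-up adding method, with flux profiles recovered by top-down
    peeling.  Includes a vegetation-index battery (NDVI, CIgreen,
    NDVIgreen, WI, WRVI, NDWI, RVIf), first-derivative spectral analysis,
    scenario generators for layered parameter profiles, a layer-count
    efficiency selector, validation statistics (bias, RMSE, linear and
    logarithmic correlation fits), and a from-scratch extended Fourier
    Amplitude Sensitivity Test (FAST) producing first-order and total-order
    indices of layered leaf area index, chlorophyll and water content per
    spectral band.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
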