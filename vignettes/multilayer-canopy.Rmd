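---
title: "Multilayer canopy reflectance, fluorescence and sensitivity analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer canopy reflectance, fluorescence and sensitivity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcanopy)
```

`mlcanopy` simulates the optical signal of a vertically heterogeneous
crop canopy — top-of-canopy (TOC) reflectance at 400–2400 nm and
sun-induced chlorophyll fluorescence (SIF) at 640–850 nm — and the
verification machinery built on top of it: vegetation indices,
layer-count selection, validation statistics and a variance-based global
sensitivity analysis.  This vignette records the model, its assumptions,
the numerical choices, and the design decisions taken where the design
was genuinely open.

## Leaf optics: the generalized plate model

A leaf is modelled as `N` identical absorbing plates separated by air
gaps (`N` is the mesophyll structure parameter, dimensionless, default
1.5, usual range 1–3).  The per-plate absorption coefficient is a linear
mix of constituent contents and specific absorption spectra,

$$k(\lambda) = \frac{C_{ab}k_{ab} + C_{ca}k_{ca} + C_w k_w +
C_{dm}k_{dm} + C_s k_s}{N},$$

with chlorophyll a+b $C_{ab}$ (µg/cm², default 40), carotenoids $C_{ca}$
(µg/cm², default 10), equivalent water thickness $C_w$ (cm, default
0.015), dry matter $C_{dm}$ (g/cm², default 0.01) and a senescent
brown-pigment fraction $C_s$ (default 0.1).  Diffuse transmission
through one plate is the hemispherical attenuation integral
$(1-k)e^{-k} + k^2 E_1(k)$ (computed with `pracma::expint`); interface
transmissivities are Fresnel coefficients averaged over a 40° incidence
cone for the upper surface and the full hemisphere internally, by
numerical quadrature.  One plate is closed by its internal
multiple-reflection series; the remaining `N − 1` plates are attached
with the classical two-flow (Stokes) closed form, with an explicit
branch for the non-absorbing case where the discriminant degenerates.
The tests verify this closed form against an independent bounce-series
oracle with quadrature-based slab transmission, and energy conservation
$\rho + \tau + \alpha = 1$ with $\alpha \ge 0$ across random parameter
draws.

**Fluorescence.**  The excitation–emission matrices are deliberately
simple: for excitation wavelength $\lambda_e$ (400–750 nm) the emitted
spectrum is the leaf's absorbed fraction at $\lambda_e$ times
$\varepsilon_1 \phi_{PSI} + \varepsilon_2 \phi_{PSII}$, where the
unit-area emission bases $\phi$ are fixed Gaussian mixtures peaking at
740 nm (photosystem I) and 685/735 nm (photosystem II), and the quantum
efficiencies default to $\varepsilon_1 = 0.004$ and
$\varepsilon_2 = 0.02$.  Each basis is additionally multiplied by a
within-leaf reabsorption escape factor: the interior transmission over
half the elementary-plate absorption depth at the emission wavelength.
Emitted photons originate throughout the leaf, and without this factor
the strong chlorophyll absorption at 685 nm would never act on them —
the canopy fluorescence spectrum would then peak near 686 nm and the
F685/F730 ratio would not decrease with chlorophyll content, both
contrary to the well-established reabsorption behaviour (and to the
package's own acceptance tests, which require a 735–745 nm peak and a
non-increasing ratio).  Half the escaping flux goes to each hemisphere,
and entries without a Stokes shift (emission ≤ excitation) are zeroed.
No re-excitation by emitted photons is modelled; fluorescence is a ≲1%
perturbation of the radiance field and the second-order term is
negligible.

## Canopy: four-stream layers, adding and peeling

The canopy is stratified into 1–60 layers of equal height, each
internally homogeneous.  Layer scattering follows the classical
four-stream SAIL formulation: leaves are azimuthally uniform with a
two-parameter inclination function (parameters `a`, `b`, defaults −0.35
and −0.15, admissible when |a|+|b| ≤ 1) discretized into the 13 standard
inclination classes; per unit LAI this yields the direct-beam extinction
`ks`, view extinction `ko`, diffuse attenuation and backscatter, the
direct-to-diffuse source terms and the bidirectional factor.  The sun is
at 45° zenith and the view nadir by default.

Each layer's operator set {tss, tsd, tdd, rsd, rdd} comes from the
analytic two-stream solution with the usual `J`-function guards near
`k = m`.  Where the diffuse eigenvalue `m = sqrt(att² − sigb²)`
vanishes (conservative scattering, ρ+τ = 1) the general solution is
numerically singular, so an exact conservative-limit branch solves the
two-stream system at `m = 0` in closed form; the branch activates below
`m < 1e-7`.  The tests drive this limit explicitly: non-absorbing leaves
over a unit-albedo soil must return TOC albedo 1 within 1e-6.

Layers are composed bottom-up by the **adding** method: the multiple
reflections between a layer and the stack below close as the geometric
series `1/(1 − rdd·Rdd′)`, which the code asserts is convergent
(spectral radius < 1; guaranteed for physical reflectances).  The
intermediate results of this recursion are exposed as the per-layer
"layer-top reflectance" curves — the reflectance of the sub-stack from
layer *i* downward including the soil — which is the natural definition
for inspecting how the signal builds from the soil upward.  The
**peeling** pass then propagates boundary fluxes top-down under unit
direct TOC irradiance; the tests check self-consistency (re-propagating
any boundary reproduces the next one to 1e-10) and a global energy audit
(reflected + absorbed by each layer + absorbed by soil = incident, to
1e-6).

Two open choices and their resolutions:

* **Reflectance convention.**  TOC reflectance is
  directional–hemispherical for direct solar incidence (`rsd` of the
  full stack).  A bidirectional quantity would require a hot-spot model;
  with a nadir view, a 45° sun, and all downstream quantities being band
  ratios, the distinction does not affect any reported number, so only
  the directional–hemispherical quantity is exposed and no hot-spot
  parameter exists.
* **Soil.**  The background is a smooth generic dry-soil spectrum rising
  linearly from 0.05 at 400 nm to 0.35 at 2400 nm, with a
  constant-albedo alternative; no site-specific soil spectrum is
  assumed.

The homogeneous-split invariance (a canopy split into K equal layers
equals the 1-layer solution to 1e-9) holds because the analytic layer
solutions form a semigroup under adding; it is tested for K = 2, 3, 5.
Heterogeneous stacks are verified against a fine-discretization
two-stream oracle (first-order thin-layer operators, 2^15 sublayers per
layer) to 1e-3.

## Leaf optical constants

Two constant sets ship with the package:

* `defaultConstants()` loads a bundled table
  (`extdata/leaf_constants_synthetic.csv`, 5-nm resolution, linearly
  interpolated to the working grid).  It is a *synthetic reconstruction*
  of leaf-level spectroscopy — in-vivo chlorophyll absorption with Soret
  and red bands decaying to zero through the red edge, carotenoid
  absorption in the blue, pure-water absorption anchored at
  Hale–Querry-style magnitudes with maxima near 1450 and 1940 nm and the
  weak 970 nm shoulder, dry matter nearly transparent in the VIS/NIR and
  rising into the SWIR, and an exponentially decaying brown-pigment
  spectrum.  It is not a redistribution of any published coefficient
  file, so absolute leaf spectra are reproducible only up to this
  coefficient choice; every verified quantity in the package is either a
  structural property or a band-ratio statistic that is robust to it.
* `syntheticConstants()` generates a minimal smooth set (Gaussian bands
  at 430/660 nm for chlorophyll, 1450/1940 nm for water, flat dry
  matter) so that the entire machinery runs with no bundled file at all;
  it is used for structural tests, not for spectra.

## Scenario generators

The generators encode the study conditions as code:

* `standardScene()` — one homogeneous layer at the standard values
  (Cab 40, Cca 10, Cw 0.015 cm, Cdm 0.01, Cs 0.1, N 1.5, LAI 3, sun 45°).
* `threeLayerStandard()` — the standard vertical profiles, top to
  bottom: LAI (0.75, 1.25, 0.05), Cab (80, 60, 40), Cw (0.02, 0.021,
  0.01) cm, carotenoids tied to chlorophyll at 25% per layer.  The LAI
  profile has its maximum in the middle layer; note the standard Cab
  profile decreases monotonically with depth instead — both are exposed
  as given, without reconciliation.
* `layerCountScenarios()` — seven scenes with 1–7 layers, the i-th scene
  taking the i-th row of the layered LAI design (total LAI 4.78 in rows
  1 and 3) and a single Cab value per scene (70 down to 5 µg/cm²), water
  fixed at 0.009 cm.
* `verificationScenes(n = 21, seed)` — synthetic three-layer scenes for
  the bias/RMSE exercise.  Each of the nine layered parameters follows a
  truncated normal within its tabulated [min, max], centred on the
  tabulated mean with sd = range/6 (so sample means land within a few
  percent of the targets); layers of the same variable are coupled by a
  Gaussian copula with correlation 0.7 so that dense scenes are dense
  throughout, and the set is ordered dense-to-sparse by total LAI.  Only
  the marginals are constrained by the tabulated bounds; the copula
  correlation is a physiological-coherence choice.
* `sweepScenes(parameter, values, mode)` — one-parameter-at-a-time
  sweeps, uniform (single layer) or layered (the standard profile
  rescaled), everything else standard.

What the generators deliberately do **not** emulate: measured field
spectra (no instrument noise, no atmospheric or soil-moisture
variability, no row structure).  Passing verification statistics on
these scenes therefore demonstrates the pipeline's internal consistency
— that the machinery detects parameter perturbations of the stated size
— not field accuracy.  The `verify` experiment makes this explicit by
comparing each scene against a replicate with 5% multiplicative
lognormal parameter noise standing in for measurement error.

## Layer-count selection and validation statistics

The efficiency score of a layer-count trial is
$E = 1/\big((T/60)\,A\big)$ with runtime `T` in seconds (the factor 60
converts to minutes, balancing the weight of time against error) and
`A` the absolute NDVI deviation from the multi-trial mean.  Runtimes are
hardware-dependent, so the selector defaults to the bundled reference
(T, A) table for reproduction and measures wall-clock only in live
mode; on the reference table the 3-layer trial is the efficiency
maximum and `selectLayers()` returns 3 (ties go to fewer layers; trials
with zero error are excluded with a warning rather than returned as
infinite scores).  Validation uses the signed relative deviation
`(simulated − measured)/simulated` and RMSE, and the correlation-fit
table regresses each vegetation index on its related parameter with a
fixed model form per index (linear for CIgreen, WI, NDWI,
WRVI(1600, 820); logarithmic for NDVI, RVI, RVIf, NDVIgreen,
WRVI(1450, 1940)) — no automatic model selection.

Vegetation indices are computed from single nearest-wavelength bands
(exact on the 1-nm grid), not sensor-convolved; the derivative spectrum
uses central differences with one-sided ends.

## Extended FAST

The sensitivity design drives each of the `k = 9` layered factors in
turn at the highest admissible frequency
$\omega_{max} = \lfloor (N_s-1)/(2M) \rfloor = 8$ along the search curve
$x = \text{lower} + (\text{upper}-\text{lower})\,
(1/2 + \arcsin(\sin(\omega s + \phi))/\pi)$ over a uniform grid of
$N_s = 65$ points (odd, $\ge 4M^2+1$ with interference factor $M = 4$),
giving exactly $9 \times 65 = 585$ model runs.  First-order indices are
the spectral power at $p\,\omega_{max}$, $p = 1..M$, over the total
power; total-order indices are one minus the power below
$\omega_{max}/2$ (the complement share).  Indices are clamped to [0, 1]
and a zero-variance output returns 0 with a warning.

**Complementary frequencies.**  The textbook extended scheme puts every
complementary factor at the same lowest frequency.  With identical
phases that makes the complements *perfectly correlated* along the
curve — they are literally the same triangle wave — which corrupts the
variance partition badly (a 4-factor linear model's indices come out
wrong by several tenths).  `fastDesign()` therefore assigns distinct
complementary frequencies `1..ceil((k−1)/2)` (capped at
$\omega_{max}/2$ so complement main effects stay under the total-order
cutoff), with at most two factors per frequency and a quarter-period
phase offset between the two — triangle waves at distinct frequencies,
or a quarter period apart at the same frequency, are exactly
uncorrelated.  Linear benchmarks of 2, 4 and 9 factors are then
recovered to better than 0.02, and the tests cross-check against an
independent brute-force pick-freeze Monte-Carlo Sobol estimator.

**Known estimator limitations** (shared, in kind, by all single-curve
FAST variants and verified by the test suite rather than hidden):

* *Total-order upward bias under complement interactions.*  Interaction
  variance between two complementary factors spreads above the
  $\omega_{max}/2$ cutoff and is misattributed to the driven factor.
  On the Ishigami benchmark this inflates the total index of the
  purely additive factor by about +0.09 at $N_s = 65$; the bias is
  structural and does not average out under phase resampling
  (`runFAST(..., resample = n)` averages indices over `n` random-phase
  curves, which does remove the first-order estimation noise).
* *Spectral leakage onto weak factors.*  A strongly saturating
  complementary factor has even-order harmonics, and at the higher
  complement frequencies these can land on the driven frequency.  In
  the canopy analysis the visible-band variance is so dominated by
  upper-layer chlorophyll that factors with physically negligible
  visible-band effects (water) inherit a leakage floor on their
  indices; orderings among such factors are numerically undefined.

**What dominance structure the physics supports.**  Across the
sensitivity bounds (total LAI between 2 and 15, Cab 10–110 µg/cm², Cw
0.001–0.03 cm), both the FAST analysis and the independent Monte-Carlo
Sobol cross-check agree: upper-layer *chlorophyll* dominates the green
(560 nm) and red (685 nm) bands — visible reflectance saturates quickly
with LAI but keeps responding to leaf absorptance — while upper-layer
*LAI* dominates the near-infrared (810 nm), where leaves barely absorb
and structure controls the signal.  Water content is nearly inert below
900 nm: pure water absorbs ~5×10⁻⁴ /cm in the visible, so a Cw of at
most 0.03 cm cannot move a visible band by more than ~10⁻⁵
reflectance.  Upper layers out-rank lower layers wherever the factor
has a resolvable effect, because light attenuates on its way down —
this is the vertical-heterogeneity premise the package exists to
explore.  Reported dominance structures that place LAI first in the
visible and water first in the near-infrared are not reproducible from
this physics; the acceptance suite states them as given and documents
the discrepancy rather than adjusting the model toward them.

## Numerical choices, in one place

* Wavelength grids: 1 nm, 400–2400 nm for reflectance; 640–850 nm for
  emission; excitation 400–750 nm.  Any strictly increasing grid works
  (constants are interpolated), which the tests exploit by running
  structural checks on 10–250 nm grids.
* Interface transmissivity quadrature: 256 nodes; slab-transmission
  oracle: 4000 nodes.
* Conservative-limit branch below `m < 1e-7`; `J1` switches to its
  series expansion when `|k−m|·L < 1e-3`.
* Adding-series divergence (`r·r′ ≥ 1`) raises an error; it cannot occur
  for physical inputs.
* Band sampling: nearest grid point; ratio indices return `NA` with a
  warning on a zero denominator rather than aborting the record.
* Seeds: every stochastic generator (`verificationScenes`, random-phase
  designs, the `verify` experiment) takes an explicit seed and restores
  the caller's RNG state.
* Problem sizes in the test suite: canopy structural tests run on
  coarse grids (10–250 nm steps); the oracle comparisons use 10 random
  scenes each; the full-resolution sweeps (7 simulations per sweep) and
  the 585-run canopy FAST run at their native sizes.

## Limitations

* One-dimensional: no row structure, clumping or hot-spot effect; the
  directional–hemispherical reflectance stands in for nadir radiance.
* No thermal emission, photosynthesis biochemistry or energy-balance
  closure; fluorescence efficiencies are fixed inputs, not
  light-responsive.
* The bundled optical constants are a synthetic reconstruction;
  absolute reflectance levels (as opposed to structural responses and
  band-ratio statistics) should not be compared against field spectra.
* Extended FAST at the minimal design size carries the total-order bias
  and leakage floors described above; conclusions about weak factors
  should lean on the Monte-Carlo cross-check.
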