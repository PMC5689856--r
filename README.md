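# ccdose

A desk-scale, CPU-only collapsed-cone convolution/superposition (S/C)
photon dose engine for radiotherapy, together with the comparison
instruments used to validate such engines: 3D gamma analysis, depth-dose
and profile extraction, chamber-style ROI mean doses, and body-surface
exclusion masks. It is aimed at medical physicists and algorithm
developers who want a transparent, fully testable S/C implementation —
the kind of engine used for independent secondary dose checks in
IMRT/VMAT patient QA — without GPU code or vendor black boxes.

## The algorithm

Dose is computed in the standard three S/C steps:

1. **Fluence.** Treatment-head transport with three sources — primary,
   extrafocal (head scatter) and electron contamination — each with its
   own spectrum and radial intensity profile. Jaws and MLC are modeled
   explicitly, including rounded leaf ends (chord-length transmission)
   and a tongue-and-groove strip. The extrafocal source is a finite
   Gaussian source, so small apertures partially occlude it and its
   fluence spills beyond the geometric field edge.

2. **TERMA.** The energy-differential fluence Ψ_E (16 energy bins) is
   ray-traced through the patient density with exact Siddon voxel
   traversal. Per voxel and bin,

   T += Ψ_b · (μ/ρ)(ED, E_b) · E_b · exp(−(μ/ρ)_w E_b · d_we) · (SAD/r)²,

   where d_we is the water-equivalent (electron-density-scaled) depth.
   Bin-wise attenuation *is* the beam-hardening model; the TERMA-weighted
   mean photon energy is recorded per voxel. For arcs, TERMA is evaluated
   every 2°.

3. **Superposition.** TERMA is spread by a point energy-deposition kernel
   h(θ, r) tabulated at 1 mm / 1° and discretized into collapsed cones
   (8 zenith × 6 azimuth by default) as a cumulative-cumulative kernel
   (CCK). Every dose voxel collects energy along each cone with the
   kernel argument equal to the *radiological* distance — the density
   scaling that distinguishes superposition from convolution — with
   optional per-voxel kernel tilting along the local ray and per-voxel
   kernel selection by recorded mean energy (hardening-aware). For arcs,
   superposition runs every 5° on TERMA accumulated at 2°.

An optional, deliberately nonphysical heterogeneity-compensated
superposition (HCS) pre-filter modifies the density near material
interfaces, one-sidedly along the beam direction, before superposition
only. It is off by default.

Gamma analysis follows the usual definition
γ = min over positions of √((Δr/δ_dta)² + (ΔD/δ_dose)²) with global or
local normalization and a low-dose cutoff, evaluated on a dta/10 offset
lattice with trilinear interpolation, and is verified against an
exhaustive brute-force oracle in the test suite.

## Worked example

```r
library(ccdose)

phantom <- build_water_cube(200, spacing = 5)          # 20 cm water cube
beam <- beam_model("6MV", dose_per_mu = 0.01)          # 1 cGy/MU reference
cfg <- engine_config(fluence_spacing = 2.5)
beam <- calibrate_output(beam, phantom, cfg)

plan <- build_square_field_plan(10, "6MV", mu = 100)   # 10 x 10 cm^2, 100 MU
dose <- calc_plan_dose(plan, phantom, beam, cfg)

grid_sample(dose, c(0, 0, 0))                          # dose at the reference point
#> [1] 1

pdd <- extract_pdd(dose)
pdd$d_max
#> [1] 15
```

The reference point receives exactly 1 Gy (100 MU × 0.01 Gy/MU) because
the output calibration closes, and the 6 MV surrogate beam builds up to
its dose maximum at 15 mm depth. A comparison of a plan against a
perturbed recalculation:

```r
noisy <- grid3d(dose$values * 1.01, dose$spacing, dose$origin)
gamma_analysis(dose, noisy, gamma_criteria(3, 2))
#> <gamma_result> 3%G/2 mm/10%: passing rate 100.00% (n = 17084)
```

A shell front end is installed with the package
(`exec/ccdose`): `ccdose phantom`, `ccdose calc`, `ccdose gamma`.

## What ships as surrogate data

Vendor beam spectra, radial profiles, the nine-material radiological
property table, and Monte Carlo point kernels are proprietary or
unpublished. The package ships clearly labelled surrogates (analytic
spectra per beam quality, NIST-style water coefficients with per-material
scale factors in `inst/extdata/materials_surrogate_v1.csv`, and
poly-exponential forward-peaked kernels). All shipped tests assert
structural physics of the engine, not agreement with any commercial
system. See the methods vignette (`vignettes/ccdose-methods.Rmd`) for the
full discussion.
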