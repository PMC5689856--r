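---
title: "The ccdose superposition/convolution engine: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ccdose superposition/convolution engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccdose)
```

# Scope and model

`ccdose` implements a collapsed-cone superposition/convolution photon
dose engine of the kind used for independent secondary dose checks of
IMRT and VMAT plans, at desk scale on a CPU. The calculation chain has
the three canonical steps — treatment-head fluence, TERMA ray tracing,
and kernel superposition — plus the verification toolkit used to
commission such engines: synthetic phantoms, percent-depth-dose
extraction, ROI mean doses, surface exclusion and 3D gamma analysis.

## Coordinate conventions

Right-handed frame in mm with the isocenter at the origin. Voxel values
live at voxel centers; `origin` is the center of the first voxel. At
gantry 0 the source sits at `(0, 0, SAD)` and the beam points down `-z`;
the gantry rotates about `y`. The water cube and slab phantoms place
their entry surface at `z = +100` mm so a gantry-0 beam at SAD 1000 mm
realizes the SSD 900 mm calibration geometry.

## Fluence

Three sources feed an isocenter-plane fluence map (default pixel 1 mm,
finer than the dose grid to resolve leaf ends):

* **Primary**: `mu * profile(r) * transmission(x, y)`, where the radial
  intensity profile is a sampled 1D table (slight horns for flattened
  beams, a Gaussian-like falloff for the FFF surrogate) and the
  transmission combines jaws and MLC. Across a rounded leaf end, the
  traversed fraction of the leaf is the chord through a cylinder of
  radius 80 mm capped at the 60 mm physical thickness, which yields the
  characteristic few-mm soft edge; transmission is
  `mlc_transmission^fraction`. A 1 mm strip at each inter-leaf boundary
  takes the more closed of the two adjacent rows (tongue-and-groove).
* **Extrafocal**: the aperture-masked primary convolved with the
  projected width of a finite Gaussian source (default sigma 20 mm at
  isocenter), scaled by `extrafocal_fraction` (default 0.08). This
  reproduces the two signature behaviors of a distributed secondary
  source: fluence beyond the geometric edge, and reduced output for
  small apertures that partially occlude the source. The test suite
  asserts both.
* **Electron contamination**: a broadly blurred aperture map deposited
  with an exponential depth falloff (`depth_constant` 10–18 mm by beam
  quality) during TERMA transport. It is additive after superposition
  and can be disabled (`engine_config(contamination = FALSE)`), which
  the kernel-physics tests do, since it is a separate empirical term.

## TERMA

One ray per fluence pixel is traced by exact Siddon voxel traversal.
Per voxel and per energy bin the released energy is
`psi_b * (mu/rho)(ED, E_b) * E_b * exp(-(mu/rho)_w E_b * d_we) * (SAD/r)^2`.
Two deliberate choices:

* **Attenuation** uses water mass-attenuation with the electron-density
  scaled path (effective pathlength); the **release factor** uses the
  local material coefficients interpolated among the nine shipped
  materials. Transport and release are thus decoupled, matching the
  standard split between "electron density attenuates the fluence" and
  "material coefficients convert fluence to released energy".
* **Beam hardening is bin-wise attenuation**, nothing more: each of the
  16 bins decays with its own coefficient, and the TERMA-weighted mean
  photon energy is recorded per voxel. The tests assert that this mean
  increases strictly with depth in water.

TERMA is deposited with path-length weighting (each crossed voxel
accumulates contribution x length, normalized by total crossing length),
so the result is invariant to fluence-plane refinement.

## Superposition

The kernel `h(theta, r)` is tabulated at 1 mm / 1 degree and collapsed
onto a cone set (default 8 zenith bands x 6 azimuths = 48 cones; a
convergence test shows the 8x6 to 16x12 PDD difference beyond build-up
is under 1%). Per cone, the radial kernel is cumulated once (CK) and
twice (CCK); interval deposition uses CK differences, with CCK providing
bin-averaged CK values where voxelization suppression is wanted.

The implementation is voxel-centric **collection**: each dose voxel
walks upstream along every cone direction in steps of one voxel size,
accumulating TERMA weighted by the CK increment over the *radiological*
interval of each step. That radiological argument is the density scaling
of superposition; with it, the engine reproduces O'Connor's theorem
(dose in a uniform half-density medium at doubled depth equals the
water dose, verified to 1%) and conserves energy globally
(`sum(D * mass) = sum(T * mass)` to 1% when the kernel reach is
contained in the phantom).

**Tilting** rotates the cone axes per voxel to follow the local ray from
the source. Numerically this is composed as (small rotation from the
beam axis to the voxel axis) x (base beam rotation); mapping the
vertical axis to the voxel axis in a single rotation is ill-conditioned
near the downward axis and broke the mirror symmetry of parallel-opposed
beams, which is why the composed form is used (the suite asserts that
symmetry at the 0.5% bound).

**Hardening-aware kernel choice**: each voxel blends the two CCKs whose
tabulated energies (default grid 0.5–8 MeV, nine values) bracket the
voxel's recorded mean energy. A nearest-kernel lookup was tried first
and rejected: the discrete kernel switch mid-build-up produced
non-physical dips of a few percent in the PDD rising region, which the
linear blend removes at a modest extra cost in the inner loop (the
suite asserts a dip-free rise).

For arcs the engine evaluates TERMA every 2 degrees (sector midpoints,
control-point MU interpolated per sector), accumulates the sectors into
5-degree groups, and superposes each group once with the group's central
axis geometry — high TERMA but low superposition angular resolution, the
standard speed/accuracy compromise for rotational delivery. A full
360-degree arc therefore performs exactly 180 TERMA evaluations and 72
superpositions, with MU conserved identically.

## Absolute calibration

`calibrate_output()` runs the full chain once under reference conditions
(10 x 10 cm^2, 100 mm depth, SSD 900 mm on the water cube) and scales
the output so the reference-point dose equals the configured
`dose_per_mu` (default 0.01 Gy/MU). The acceptance suite re-runs the
chain from scratch and requires closure within 0.2%; calibration is
idempotent and linear in `dose_per_mu`.

## HCS

Heterogeneity-Compensated Superposition is exposed as an optional,
explicitly nonphysical density pre-filter seen *only* by superposition
(TERMA always uses raw density). The published descriptions state that
the patient density near interfaces is modified in a position- and
direction-sensitive way but give no formula, so the filter here is an
original parameterized stand-in with that stated character: along lines
parallel to the beam, electron-density steps of at least
`interface_threshold` (default 0.25) trigger a one-sided blend of the
downstream density toward the upstream flank value with weight
`strength * exp(-3 s / window)` up to `window_mm` (default 10 mm)
from the interface. Consequences that are guaranteed by construction and
tested: `strength = 0` is the identity, voxels beyond the window are
bit-exact, and filtered values stay within the two flank densities.

Everything asserted about HCS in this package is an engine-internal
property — e.g. that on the slab phantom it changes the dose in the
homogeneous entrance region by less than 0.5% while moving the in-lung
dose — never a fidelity claim to any vendor implementation. It defaults
to off, and the filter is applied per beam direction (a per-beam
pre-pass; a per-cone variant would multiply the cost by the cone count
for no tested benefit). Oblique beams filter along the grid axis nearest
the beam direction; the interface geometries of interest here (slab and
thorax phantoms) are axis-dominant, and a fully oblique resampling
filter was not worth its interpolation artifacts.

## Gamma analysis

The reference grid defines the evaluation lattice; the evaluated grid is
sampled trilinearly. The search runs over a `dta/10` offset lattice
capped at `3 * dta`, sorted by radius with an exact early-termination
bound (once the spatial term alone exceeds the current best, no later
offset can win). The brute-force oracle searches the same lattice in raw
order with only a lossless dominance prune (offsets whose spatial term
exceeds the zero-offset gamma cannot be minimizers), so optimized and
brute-force results agree identically on every voxel; the acceptance
suite checks 100 randomized grid pairs. The low-dose cutoff applies to
the reference grid (voxels below the cutoff are `NaN` in the gamma map
and excluded from the passing rate), and the dose criterion is
`dose_pct` of the reference global maximum (global mode) or of the local
reference dose (local mode).

# Synthetic phantoms and plans

The fixtures module generates every geometry used by the validation
protocol, deterministically:

* **Water cube**: 20 x 20 x 20 cm^3, ED 1.0 — calibration and basic
  beams.
* **Slab phantom**: 5 cm water / 5 cm lung (ED 0.3) / 20 cm water,
  >= 30 cm wide — interface and lateral-disequilibrium behavior.
* **Thorax phantom**: 30 x 30 x 20 cm elliptical body (ED 1.0), two
  lung cylinders (ED 0.21) along the superior-inferior axis, optional
  4 cm diameter unit-density spherical target centered in the right
  lung. Only the overall dimensions and densities of the commercial
  phantom are published; the interior layout here uses lung cylinders
  of 55 mm radius centered 75 mm laterally. (A wider 80 mm radius was
  considered and rejected: at +/-70 mm centers the two cylinders would
  overlap each other and pierce the body outline, which no two-lung
  phantom does.) With the target present the grid is centered on the
  target, matching isocenter-at-target setups.
* **Plans**: jaw-defined open squares (with an optional MLC-defined
  square inside a larger jaw opening), a five-beam coplanar lung plan
  (equispaced gantry angles, equal MU, MLC disks of 27 mm radius = 20 mm
  target + 7 mm margin), and full arcs with inclusive control-point
  endpoints (181 control points at 2 degrees; the first carries no MU).

What these fixtures do **not** emulate: CT noise and artifacts, real
patient heterogeneity textures, couch and immobilization hardware,
non-coplanar geometry, and the rod inserts of the physical thorax
phantom. Tests passing on these phantoms therefore demonstrate the
engine's internal physics (conservation, scaling, symmetry, interface
behavior), not clinical agreement on real CT data.

# Surrogate data

Four data sets that a commercial engine ships as commissioning data are
unpublished, and are replaced by clearly labelled surrogates:

* **Spectra** (`surrogate_spectrum`): `E exp(-E/Ec)` truncated at the
  nominal potential, with `Ec` = 0.85 / 1.35 / 2.2 MeV for 6 MV, 10 MV
  FFF and 15 MV. These produce strictly increasing fluence-mean
  energies and, on the shipped kernels, strictly ordered build-up
  depths — the qualitative ordering expected of the three beam
  qualities, and what the suite asserts.
* **Materials** (`inst/extdata/materials_surrogate_v1.csv`, version 1):
  water mass attenuation and energy absorption at the 16 bin energies
  from standard published compilations, scaled per material (air 0.90,
  soft tissues 0.98–1.00, bones 1.00–1.05 with a mild energy tilt,
  metal surrogate up to 1.26). Nine materials from air (ED 0.001) to a
  metal surrogate (ED 4.0), water exactly at ED 1.
* **Kernels** (`kernel_table`): forward-peaked poly-exponential family;
  angular weight `exp(-theta/theta0)` with
  `theta0 = 40 / sqrt(1 + E)` degrees, radial exponential with forward
  range `6 E` mm blending to about 1 mm backward, tabulated to 60 mm
  and renormalized. The 60 mm reach truncates the faraway tail of
  high-energy kernels; renormalization folds that energy back so
  conservation holds by construction.
* **Beam model constants**: extrafocal fraction 0.08, contamination
  amplitudes 0.05–0.08, MLC transmission 0.016, jaw transmission 0.002,
  120-leaf bank approximated as 40 central 5 mm pairs.

# Numerical choices

* Fluence plane 1 mm (default), engine tests 2–2.5 mm; fluence pixels
  should not exceed the dose voxel size.
* Superposition ray step = smallest voxel dimension; collection stops
  when the radiological radius reaches the kernel tabulation (60 mm) or
  the ray leaves the grid.
* CT-to-ED conversion is piecewise linear with end clamping; density
  overrides from structures win over converted values.
* Ties in `d_max` resolve to the shallowest depth; PDD normalization
  uses the first sampled depth at least 20 mm beyond `d_max`.
* Gamma search step `dta/10`, cap `3 * dta` (oracle-verified); the
  brute-force guard refuses reference grids above 50k voxels.
* Erosion (`surface_exclusion`) uses a discrete grid-metric ball; with
  voxels coarser than the margin the ball contains no neighbors and the
  mask is returned unchanged — use a grid at least as fine as the
  margin.
* DICOM RT Dose support is a deliberate subset: explicit VR little
  endian, GRID type, uniform frame offsets, 32-bit scaled integers.
  Non-uniform `GridFrameOffsetVector` is rejected rather than resampled.

Problem sizes in the shipped tests (water cube at 5 mm, slab at
5 x 5 x 2.5 mm, 20^3 gamma grids, arcs on a 10 mm cube) were chosen as
the coarsest settings at which each property is still cleanly resolved;
every tolerance in the tests was met at these settings without per-test
tuning.

# Known limitations

* The kernels, spectra and material factors are surrogates: absolute
  PDD shapes and output factors are plausible, not commissioned, and no
  claim of agreement with measurements or any commercial system is made
  or tested.
* Kernel selection by per-voxel mean energy is a point approximation of
  polyenergetic superposition; per-bin superposition would cost a
  factor of 16.
* Electron contamination is an empirical surface term, not transport.
* The collection walk samples density and TERMA at nearest voxels; very
  thin high-contrast laminae below the step size can be skipped.
* HCS is a stand-in filter; see above.
* No wedges, no couch or collimator rotation, no interleaf leakage map
  beyond the tongue-and-groove strip, no monitor-chamber backscatter.
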