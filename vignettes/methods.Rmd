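---
title: "Voronoi-branch lung phantoms and proton range mixing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voronoi-branch lung phantoms and proton range mixing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A proton beam stopping in a heterogeneous medium such as lung does not keep
the sharp distal edge it has in water. Ray to ray, the water-equivalent path
length (WEPL) through the medium fluctuates, so the Bragg peaks of the
individual rays stop at slightly different residual depths. The superposed
depth-dose curve has a lower peak and a wider distal falloff -- *range
mixing*. The quantities of interest are:

* **DFW** (distal falloff width): the distance over which the depth dose
  drops from 80% to 20% of its maximum, distal of the peak;
* **peak value**: the maximum of the degraded curve as a percentage of the
  pristine maximum;
* **sigma bookkeeping**: under the approximation that the widening is
  Gaussian with standard deviation $\sigma$, $\mathrm{DFW} \approx 1.13\,
  \sigma$ (the 80--20 drop of a Gaussian *bump* spans
  $\sigma\,(\sqrt{2\ln 5}-\sqrt{2\ln 1.25}) = 1.126\,\sigma$), widths add in
  quadrature, $\sigma_\mathrm{total}^2 = \sigma_\mathrm{pristine}^2 +
  \sigma_\mathrm{hetero}^2$, and for a medium of average density $p$
  (used dimensionlessly), thickness $z$ and structure size $\Delta$ the
  binomial structure model gives $\sigma^2 = (p - p^2)\, z\, \Delta$.

`vorolung` builds a 3D-printable lung phantom that realizes such a medium --
the edge skeleton of a centroidal Voronoi tessellation (CVT), printed in
resin at lung bulk density -- and predicts its range-mixing effect with a
deliberately simple per-ray WEPL transport model.

## Phantom design

**Geometry.** Generating points are placed in a 4 cm cube by Poisson-disk
dart throwing (minimum spacing $0.75\,(V/n)^{1/3}$, a standard feasibility
margin for dart throwing) and relaxed by Lloyd's algorithm toward a CVT, so
that cells are uniform and the structure has no preferred direction. The
phantom is the 1D edge skeleton of that tessellation clipped to the cube:
the segments where three Voronoi cells meet, with a boundary node inserted
where an edge crosses a cube face. Only the largest connected component is
kept; a disconnected fragment would be unprintable. Traces of clipped
Voronoi faces on the cube surface can be added (`include_surface = TRUE`)
but are excluded by default: they are not part of the skeleton, and on the
beam-parallel faces they would lay long material runs along the beam axis.

**Lloyd relaxation on a fixed sample cloud.** Cell centroids are estimated
on a uniform Monte Carlo cloud ($10^5$ points by default) drawn once per
call. Freezing the cloud makes every iteration an exact Lloyd/k-means step
on that empirical distribution, so the recorded quantization energy is
provably non-increasing -- with fresh samples per iteration the trace would
only be stochastically decreasing. The stopping tolerance (maximum point
movement $10^{-3}$ cm) is rarely reached before the iteration cap of 30;
the cap governs in practice, which is fine because the phantom only needs
CVT-like uniformity, not a converged CVT.

**Voronoi construction.** No 3D Voronoi library is part of this package's
dependency stack, so the diagram is built directly: for each generator, the
cell clipped to the cube is reconstructed by solving all triples of
candidate planes (bisectors toward the 45 nearest neighbours plus the six
cube faces), keeping solutions that satisfy every candidate half-space and
are globally closest to that generator. The global closeness test makes
false vertices impossible regardless of the neighbour cutoff; the cutoff
only needs to exceed the true number of cell neighbours, which is about 15
for CVT-relaxed points. The test suite checks this construction against an
independent brute-force Delaunay dual (all empty-circumsphere tetrahedra of
$n \le 8$ points, circumcenters joined across shared faces, hull rays
clipped to the cube).

**Radii.** Edge radii are drawn uniformly in 0.2--0.4 mm (half the printed
0.4--0.8 mm diameters); the radius distribution across branches is not
reported for the reference design, and a uniform draw over the printed
range is the least committal choice. Joints are spherical caps of twice the
largest incident branch radius, capped at 0.8 mm radius, reproducing the
"thicker joints up to 1.6 mm diameter" morphology and making the structure
sizes span 0.4--1.6 mm -- exactly the $\Delta$ range over which the
binomial model brackets $\sigma$.

**How many generating points?** The point count is *not* a free texture
knob. The printed branch diameters (0.4--0.8 mm) and the target bulk
density (0.237 g/cm^3 of 1.11 g/cm^3 resin) together fix the total branch
length: the structure must occupy $(0.237/1.11) \times 64\ \mathrm{cm}^3
\approx 13.6\ \mathrm{cm}^3$, and at mean radius 0.3 mm that requires
roughly $L = 13.6 / (\pi \overline{r^2}) \approx 4.6\times 10^3$ cm of
branch. Empirically the clipped CVT skeleton supplies $L \approx 5.6\,
n^{2/3} V^{1/3}$, giving $n \approx 3000$. With the default
`n_points = 3000` the density-tuned diameters stay essentially inside the
printed range; with, say, 1000 points the tuner must inflate diameters to
about 0.5--1.0 mm to reach the same density, leaving the printed range and
coarsening the texture (and with it the range-mixing signal, since the
structure size is what sets $\sigma_\mathrm{hetero}$).

**Density tuning.** A single global multiplicative factor on all radii is
found by bisection so that the voxelized fill fraction times the material
density (plus the air term, 0.0012 g/cm^3) meets the target within 0.05%
relative -- half of the 0.1% design-error budget. Scaling radii rather than
resampling geometry preserves the topology. Radii leaving the printable
range are reported, not clamped: the print check is the designer's call.

## Voxelization

The capsule union (segments plus joint spheres) is rasterized on the
100^3 grid of 0.4 mm voxels used for all headline numbers. Each voxel
stores the fraction of a stratified $4^3$ subsample falling inside the
union; voxels farther than half a voxel diagonal from every surface are
resolved exactly by a centre test. Density accounting uses the fractional
grid (an exact identity); transport consumes the binary map thresholded at
0.5, the two-material (resin / air) model a Monte Carlo code would use.
Voxel extents are half-open with 0-based indexing; a network translated by
exactly one voxel pitch shifts the occupancy by one voxel.

Printable surfaces are extracted by marching tetrahedra (six-fold Kuhn
subdivision, conforming across the lattice, vertices deduplicated per
lattice edge, hence watertight) over the signed distance field of the
capsule union, with the outermost lattice shell forced positive so that
branches reaching the cube faces are capped. Output is binary STL; grids
are written as MetaImage (binary occupancy, 8-bit) and NRRD (fractional,
float).

## Beam model

The pristine Bragg curve is an analytic power-law stopping profile,
$D_0(z) \propto (R-z)^{-0.435}$ for $z < R$ (the exponent follows from the
$R \propto E^{1.77}$ range-energy relation), stored as exact bin averages
on a 0.02 cm grid and convolved with a Gaussian of width
$\sigma_\mathrm{pristine}$ representing range straggling plus beamline
energy spread, folded together because only their sum is observable.
Default ranges are 15.6 cm (155 MeV) and 25.9 cm (200 MeV) from standard
range-energy tables; every headline metric depends only on the distal-edge
shape, not the absolute range. A measured pristine curve can be supplied as
CSV instead.

This family is self-similar: its 80--20 falloff is $1.316\,\sigma$
regardless of $\sigma$. That differs from both conversion constants the
analysis side exposes -- 1.13 (Gaussian bump) and 1.683 (Gaussian edge) --
and the package deliberately keeps all three distinct. Calibration
therefore never trusts a shape constant: `calibrate_sigma_to_dfw()` bisects
on $\sigma$ until the *measured* falloff of the generated curve matches the
target (0.24 cm at 155 MeV, 0.36 cm at 200 MeV) within half a bin. The
calibrated $\sigma$ at 155 MeV is 1.81 mm; dividing the same DFW by 1.13
gives 2.12 mm. Both numbers are "the sigma" under different conventions,
which is exactly why the conversions carry distinct names.

SOBPs are weighted sums of range-shifted copies of the pristine curve
(pure translation; the slight sigma reduction of shallower constituent
peaks is neglected), with non-negative least-squares weights targeting a
flat plateau; flatness worse than 2% over the central 90% of the width is
reported, not hidden. No reference weighting scheme is available for the
hardware being mimicked, so no SOBP quantity is treated as a reproduction
target.

## Transport model and its scope

Degradation is modeled purely as per-ray range mixing. Rays parallel to the
beam axis are cast on a jittered lateral grid (jitter breaks voxel-lattice
aliasing); each ray accumulates WEPL exactly over its voxel column with
RSP = density ratio (resin 1.11, air 0.0012 -- the true resin stopping
power differs by a few percent, but a bulk RSP error only translates the
curve and cancels from DFW and peak metrics). The degraded curve is the
ray-average of the pristine curve shifted per ray, normalized to the
pristine maximum. Multiple Coulomb scattering, nuclear interactions and ray
crossing are deliberately outside the model: the binomial closed form the
results are compared against is itself exactly this approximation.

Two scope notes matter when comparing to measured values:

* **Lateral rim.** Within about one cell spacing of the lateral faces the
  clipped skeleton cells are systematically under-dense (the printed
  phantom is not: its faces carry the printed surface net). The default ray
  grid therefore excludes a 0.3 cm rim -- the quantity of interest is the
  range mixing of the lung texture, not a finite-cube boundary artifact.
  `margin_cm = 0` restores full-face coverage.
* **Scoring.** Only relative falloff geometry is modeled; detector response
  and measurement-plane details are not. Depth binning is 0.02 cm
  everywhere, so widths are meaningful to about one bin.

The homogeneous-slab comparator applies one uniform shift (thickness times
density ratio): bulk density alone, with no heterogeneous structure, leaves
the falloff width untouched by construction -- the null result that
motivates heterogeneous phantoms in the first place.

## Numerical choices

* Falloff crossings are located by linear interpolation; with noisy tails
  the first crossing after the global maximum is used, and an isotonic
  (monotone) smoothing of the distal tail is available behind
  `smooth = TRUE`.
* Degradation bins per-ray shifts to 5 um before interpolating -- two
  orders below the depth bin.
* Bisections (density scale, sigma calibration) run to tolerances of 0.05%
  relative and half a depth bin respectively, each half of the
  corresponding acceptance budget.
* All randomness flows through named integer seeds (`spec$seed` for design,
  `jitter_seed` for rays, explicit seeds for radius draws and oracles);
  repeated runs are bit-identical.
* Problem sizes for the shipped analyses: 100^3 voxels with $4^3$
  supersampling, about $1.3\times 10^4$ rays at 0.3 mm pitch, $10^5$ Lloyd
  samples, $10^5$ oracle columns. These match the scales at which the
  reference quantities were reported, while keeping a full design-and-
  transport cycle to a few minutes on one core.

## What the generator does and does not emulate

The synthetic phantom reproduces the *statistical* features the range-
mixing argument needs: correct bulk density to 0.1%, branch and joint
diameters spanning 0.4--1.6 mm, isotropic CVT texture, two-material
composition. It does not reproduce airway-tree anatomy, printer slicing or
support-material residue, CT calibration of the printed part, or organ
motion. Passing tests therefore demonstrate that the *model chain*
(geometry to voxels to WEPL statistics to degraded curve) reproduces the
published degradation numbers under the published design conditions; they
do not validate the transport simplifications against a full Monte Carlo
or measurement beyond those tabulated endpoints.

## Known limitations

* The per-ray model slightly overestimates range mixing relative to a full
  transport calculation, since lateral scattering inside the absorber
  averages neighbouring columns; at these structure sizes the effect is at
  the edge of the DFW tolerance.
* The printed sigma bookkeeping at 200 MeV is internally inconsistent at
  the last digit in its source (a pristine sigma of 3.13 mm where
  0.36 cm / 1.13 gives 3.19 mm); the package reproduces the arithmetic
  from the printed inputs (4.24, 3.13) and leaves the discrepancy
  documented rather than resolved.
* Binary voxelization at 0.4 mm coarsens sub-voxel branches (partial-volume
  effect); the fractional grid is retained so density accounting does not
  inherit that bias.
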