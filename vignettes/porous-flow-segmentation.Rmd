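---
title: "Segmenting volumetric images by porous-media flow: model, numerics and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting volumetric images by porous-media flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroseg)
```

## The idea

Intensity thresholding segments a greyscale volume by drawing a hard
surface through a soft transition: voxels on a fluid–tissue boundary
average both materials (the partial volume effect), so any single
intensity cut is a half-voxel guess.  `poroseg` instead interprets the
image as a porous medium, lets a viscous fluid creep through it, and reads
the object boundary off the computed velocity field, which decays smoothly
and steeply across the physical boundary.  The payoff is sub-voxel surface
definition and robustness to noise, at the cost of one linear PDE solve.

## Model

### Intensity to porosity

With pure-fluid and pure-tissue reference intensities $I_f$ and $I_s$
(either orientation; contrast-filled lumina are bright, airway air is
dark), the linear mixing model gives the per-voxel fluid fraction

$$\varepsilon = \frac{I_v - I_s}{I_f - I_s},$$

clipped to $[0,1]$.  Clipping is our choice: local intensity overshoot
(noise, calcifications) otherwise produces nonphysical fractions.  A
conservative *coarse intensity range* (closed interval, user-supplied)
first discards voxels that cannot belong to the object; the final surface
is insensitive to its exact bounds because out-of-range voxels would carry
enormous resistance anyway.  Voxels with $\varepsilon \le 0.1$ (closed
inequality) are declared solid and removed from the domain — the
resistance law below is singular as $\varepsilon \to 0$, and flow through
such voxels is negligible.

### The shrunken-voxel resistance

A boundary voxel of edge $d$ is modelled as a fluid slab of height
$\varepsilon d$ over a solid slab of height $(1-\varepsilon)d$.  Its
hydraulic radius is $\varepsilon d$, and the Hagen–Poiseuille/Ergun
derivation then yields a friction-factor relation
$f_b = A/\mathrm{Re}_b + B$ with

$$f_b = \frac{\Delta p}{L}\frac{\varepsilon d}{\rho v^2},\qquad
  \mathrm{Re}_b = \frac{\varepsilon \rho v d}{\mu}.$$

The constants are semi-empirical.  The package determines them the same
way it would for a packed bed, but with numerical experiments instead of
physical ones: steady creeping flow is solved in 2-D channels whose fluid
strip has height $\varepsilon d$ (no-slip bottom where the solid slab
sits, shear-free symmetry top, fully developed half-parabolic inflow), and
the measured pressure gradients are non-dimensionalised and fitted by
unweighted least squares in the $(1/\mathrm{Re}_b, 1)$ design.  The fit
returns $A = 3$ (to a fraction of a percent at 64 cells across the strip)
and an inertial constant $B$ indistinguishable from zero in the creeping
regime — both also follow exactly from the plane-Poiseuille closed form
$\Delta p/L = 3\mu v/(\varepsilon d)^2$, which the package carries as the
analytic oracle for the numeric solver.

Subtracting the fully fluid reference voxel and converting physical to
superficial velocity ($v = v_s/\varepsilon$) gives the per-voxel viscous
resistance used in the flow solve:

$$P_v = 3\,\frac{(1-\varepsilon)^2}{\varepsilon^3 d^2}\,\mu .$$

The data model retains an inertial resistance slot, defaulted to zero
because the calibrated $B$ vanishes.

Why not model the voxel as a bed of spherical particles?  Non-dimensionalising
the *same* simulated pressure drops with the packed-bed hydraulic radius
spreads the porosities onto distinct lines (the per-porosity fitted
constants have a coefficient of variation above 0.6 in our campaign),
whereas the shrunken-voxel form collapses them onto the single hyperbola
$f_b\,\mathrm{Re}_b = A$.  `collapseDiagnostic()` quantifies this dichotomy,
and the packed-bed formulas are retained for that comparison only.

### Flow solve

The solver treats steady incompressible creeping flow with a distributed
momentum sink (Stokes–Brinkman):

$$\nabla\cdot v_s = 0, \qquad
  0 = -\nabla p + \mu \nabla^2 v_s - P_v\, v_s .$$

Dropping the convective term is a deliberate deviation from a
general-purpose laminar solver: the method operates at $\mathrm{Re}<1$
precisely so the flow fills the domain without inertial effects, and the
linear system is deterministic and fast.  The effective Brinkman viscosity
equals $\mu$ (no enhancement).  Boundary conditions follow the method's
setup: uniform normal inlet velocity ($10^{-4}$ m/s by default), zero
outlet pressure, no-slip walls everywhere else; symmetry sides are
available for verification cases.  Working-fluid presets (`blood`, `air`,
`unit`) matter only through the ratio $\rho/\mu$ in the (tiny) Blake
number $Bl = (\rho u d/\mu)\,\varepsilon/(1-\varepsilon)$; near-wall
voxels sit at $Bl \ll 1$, so segmentations are insensitive to the fluid —
`blakeNumber()` lets you check this per voxel.

### Iso-value selection

The speed field is swept with 33 log-spaced iso-values over
$[10^{-14}, 10^{-6}]$ m/s.  At each value the level-set volume $V$ and
area $A$ are matched to a model sphere, giving radius changes relative to
a reference iso-value $\mathrm{iso}_0$:

$$dR = \left(\tfrac{3V}{4\pi}\right)^{1/3} - R_0, \qquad
  dr = \sqrt{\tfrac{A}{2\pi}} - r_0 .$$

The area model deliberately uses the constant $2\pi$ as the method
prescribes; it rescales $r_0$ and $dr$ jointly and cannot move plateau or
inflexion locations, which are all the selector uses.  By convention
$\mathrm{iso}_0$ is one order of magnitude below the inlet speed for
compact objects and equal to the inlet speed for complex, airway-like
ones (the anatomy presets encode this).

As the iso-value decreases, $dR$ and $dr$ change quickly while noise
voxels accrete, plateau while the surface sits in the steep near-wall
velocity gradient, and may turn up again at extreme thresholds.  The
selector declares plateau segments where the slope against
$\log_{10}(\mathrm{iso})$ falls below 5% of the sweep's maximum slope (a
documented, overridable stand-in for the visual judgement the method
otherwise requires), then returns the plateau's low-iso end when a
terminal upturn follows ("plateau-inflexion") and the plateau start
otherwise ("plateau-start" — the behaviour seen when coarse thresholding
already removed the background noise).  Ties between equally long plateaus
resolve towards lower iso-values.  $dr$ can be chosen as the driving
indicator for scroll-like geometries, whose area responds more sharply to
the threshold than their volume.

## Numerics

*Discretisation.*  Marker-and-cell staggered grid on the (isotropically
resampled) voxel lattice: face-normal velocities, cell-centred pressures,
7-point Laplacians, face resistance as the mean of the adjacent cell
$P_v$.  Tangential no-slip at walls uses half-cell mirror ghosts; outlet
faces carry a zero ghost pressure and zero normal velocity gradient.  The
discretisation is second order: the open-duct solve matches the
rectangular-duct Poiseuille series to 0.3% at 24 cells across, and the
2-D channel matches the closed form to 0.01% at 64 cells.

*Linear solve.*  The saddle-point system is solved directly (sparse LU)
for small or effectively 2-D problems, and otherwise by conjugate
gradients on the pressure Schur complement with the three velocity blocks
Cholesky-factored once and a Jacobi-style preconditioner
$\operatorname{diag}(S) \approx \sum_f G_{fc}^2/A_{ff}$.  The Schur
residual *is* the continuity residual, so the convergence tolerance
(default $10^{-8}$ relative, $10^{-10}$ in verification runs) directly
bounds the mass imbalance.  There is no random initialisation anywhere:
solutions are bitwise reproducible.

*Degenerate cells.*  Isolated fluid cells (no fluid neighbour) are
reassigned to solid with a logged count, and fluid components with no path
from an inlet are removed — they would carry zero flux and only add a
pressure nullspace.  A domain whose inlets and outlets are disconnected is
an error, not a silent zero.

*Iso-surfacing.*  Surfaces are extracted by marching tetrahedra (each
cube split into the six Kuhn tetrahedra, linear interpolation along
edges, edge-keyed vertex dedup), which yields watertight, consistently
outward-oriented meshes without the classic cube-case ambiguities.  The
speed grid is padded with zeros so level sets touching the domain
boundary close; enclosed volume comes from the divergence theorem.
Largest-component filtering discards satellite noise blobs by default.
Cloud-to-mesh (C2M) distances are exact point-to-triangle distances
accelerated by a uniform grid, normalised by the *original* in-plane
pixel size — the scanner resolution is the meaningful yardstick, not the
upsampled grid.

## The phantom generator

Because clinical image datasets are generally not redistributable,
every pipeline stage is validated on synthetic phantoms with
known ground truth: analytic solids (spheres, capsules, torus segments,
Y-bifurcations) voxelized by stratified sub-sampling (fluid fraction per
voxel, exact 0/1 away from boundaries), rendered to intensity by the same
linear mixing model the conversion inverts, then optionally blurred along
z (slice-thickness smearing), and corrupted with seeded Gaussian noise
and speckle blobs.  Ground truth is delivered as the exact signed-distance
function plus a finely tessellated reference mesh, so C2M evaluation is
against an effectively exact reference.

The standard study is a 64³ sphere-on-tube phantom at 0.1 mm spacing with
intensity contrast 200 over 0 and noise sd 10 (contrast-to-noise ≈ 20,
mid-range for clinical CT angiography), plus a handful of speckle blobs.
The pipeline's selected iso-surface recovers its boundary with mean and
standard deviation of the C2M distance below one voxel — sub-voxel
agreement with the known truth.  What these
phantoms do *not* emulate: beam hardening, reconstruction-kernel
correlations, motion artefacts, and anatomy-scale intensity
inhomogeneity.  Passing tests therefore demonstrate the pipeline's
correctness and noise robustness, not clinical-grade validation.

## Problem sizes and defaults

| Quantity | Default | Why |
|---|---|---|
| Solid cutoff $\varepsilon_{\min}$ | 0.1 | resistance singular below; negligible flow |
| Inlet speed | $10^{-4}$ m/s | keeps $\mathrm{Re} < 1$ (creeping regime) |
| Sweep | 33 values, $10^{-14}$–$10^{-6}$ m/s | method's range; log-spaced |
| Plateau threshold | 5% of max slope | documented stand-in for visual judgement |
| Target spacing | 0.1 mm (vessels), 0.25 mm (airways) | anatomy presets |
| Solver tolerance | $10^{-8}$ relative | bounds mass imbalance directly |
| Calibration campaign | $d \in \{0.25, 1\}$ mm, $\varepsilon \in \{0.3,...,0.9\}$, 4 velocities | the relation is exact, not statistical; a reduced grid suffices |

The calibration uses the blood preset; the fitted $A$ is
fluid-independent in the creeping regime (a property the tests check).
Verification problems are sized for a desk machine: 64-cell channel
solves, 32-cell duct sections, 64³ phantoms — each well inside a minute
to a few minutes on one CPU.

## Known limitations

- Anisotropic voxels must be resampled before the porous model; the
  resistance law assumes one edge length $d$.
- The downstream clinical pipeline (bi-Laplacian smoothing, inlet/outlet
  extrusion, CFD-ready meshing, wall-shear post-processing) is out of
  scope, as are comparisons against active-contour/watershed-style
  segmenters.
- No slip-interface (Beavers–Joseph) wall treatment; the Brinkman layer
  is resolved, not modelled.
- Narrow passages (≲ 2 voxels) carry inherently slow flow and may merge
  or pinch off at any single iso-value — the same failure mode the method
  shows on constricted nasal passages; `selectIso()` supports a manual
  override for such cases.
- DICOM series are not read directly; convert to NIfTI or MetaImage
  first.
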