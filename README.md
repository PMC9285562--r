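# poroseg: porous-media flow segmentation of volumetric images

`poroseg` segments tubular and saccular structures — vessel lumina in
contrast CT angiography, airways, other fluid-filled anatomy — from
volumetric greyscale images by a physics-based route instead of an
intensity threshold.  It is aimed at researchers preparing patient-specific
geometries (e.g. for haemodynamic simulation) who want sub-voxel surface
definition that is robust to noise and partial-volume blur.

## The method

1. **Intensity to porosity.**  A voxel straddling the fluid–tissue boundary
   mixes both intensities linearly (the partial volume effect), so the
   fluid fraction of each voxel is

   ε = (I_v − I_s) / (I_f − I_s),  clipped to [0, 1],

   where I_f and I_s are the pure-fluid and pure-tissue reference
   intensities.  Voxels with ε ≤ 0.1 are treated as entirely solid and
   removed from the computational domain.

2. **Porosity to viscous resistance (shrunken-voxel model).**  Each
   boundary voxel is modelled as opposing solid and fluid slabs; relative
   to a fully fluid voxel the calibrated Darcy-type viscous resistance is

   P_v = 3 (1 − ε)² / (ε³ d²) · μ   [kg m⁻³ s⁻¹],

   with d the isotropic voxel edge (m) and μ the fluid viscosity.  The
   constant 3 and the vanishing inertial constant are recovered by the
   package's own calibration: creeping-flow solves of partially blocked
   2-D channels, non-dimensionalised as a friction factor
   f_b = (Δp/L)·εd/(ρv²) against a bed Reynolds number Re_b = ερvd/μ, and
   fitted as f_b = A/Re_b + B.

3. **Creeping flow.**  Steady incompressible Stokes–Brinkman flow
   (∇·v = 0, 0 = −∇p + μ∇²v − P_v v) is solved on the voxel grid with a
   staggered finite-volume discretisation: uniform inlet velocity
   (default 10⁻⁴ m/s), zero outlet pressure, no-slip walls.

4. **Velocity iso-surface segmentation.**  The object boundary is a level
   set of the speed field.  Sweeping iso-values from 10⁻⁶ down to
   10⁻¹⁴ m/s, the segmented volume V and area A are matched to a model
   sphere; the radius changes dR (from V) and dr (from A) plateau where
   the surface is insensitive to the threshold, and the plateau
   end/inflexion marks the segmentation value.  The surface is extracted
   by marching tetrahedra and exported as STL/PLY/OBJ.

Segmentation quality is evaluated as the cloud-to-mesh (C2M) distance
between the extracted surface and a reference, normalised by the original
in-plane pixel size.

## Worked example

Everything below is generated in code — no external data needed.  A noisy
sphere-on-tube phantom (64³ voxels at 0.1 mm, fluid intensity 200 over
background 0, Gaussian noise sd 10, i.e. contrast-to-noise ≈ 20) is
segmented end-to-end:

```r
library(poroseg)

ph  <- aneurysmPhantom(dims = 64L, tubeRadius = 0.8, sacRadius = 1.4,
                       spacing = 0.1, noiseSd = 10, speckleCount = 6L,
                       seed = 7L)
cfg <- pipelineConfig(input = ph$image, coarseRange = c(50, 250),
                      If = 200, Is = 0, preset = "aneurysm",
                      targetSpacing = NA)
res <- runPipeline(cfg)
#> coarse threshold retains 24692 voxels
#> solidify (eps <= 0.1) leaves 24692 fluid voxels
#> solved: relative mass imbalance 3.94e-10
#> selected iso = 3.162e-10 m/s (plateau-start)

res$mesh
#> SurfaceMesh: 23982 vertices, 47960 triangles, 1 component(s)
#>   watertight: TRUE  area (mm^2): 70.372  volume (mm^3): 27.38

cloudToMeshDistance(res$mesh, ph$mesh, pixelSizeMm = 0.1)
#>      mean       max        sd         n
#>    0.6707    1.9249    0.3033 23982.0000
```

The selected iso-surface reproduces the known phantom boundary with mean
and standard deviation of the C2M distance well below one voxel.  The
calibration that fixes the resistance constant is one call:

```r
runCalibration()$fit
#> FitResult: A = 2.99969  B = 5.63e-12  rms = 4.3e-11  (n = 32)
```

A thin CLI with `segment`, `calibrate`, `phantom`, `evaluate` and
`sweep-report` subcommands is installed under `inst/scripts/poroseg`.

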