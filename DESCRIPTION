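Package: poroseg
Title: Porous-Media Flow Segmentation of Volumetric Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physics-based segmentation of tubular and saccular structures
    (vessel lumina, airways) in volumetric greyscale images. Voxel intensity
    is translated to a porosity via a linear partial-volume model, porosity to
    a viscous porous resistance via the shrunken-voxel law, and steady
    creeping incompressible flow (Stokes-Brinkman) is solved on the voxel
    grid. The target object is extracted as a velocity-magnitude iso-surface,
    with the iso-value chosen from a spherical-model dR/dr indicator curve.
    Includes the single-voxel channel calibration of the shrunken-voxel
    constants, ground-truthed synthetic phantoms with partial-volume
    rendering, slice blur and noise, marching-tetrahedra surface extraction,
    and cloud-to-mesh distance evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
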