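#' Construct a VolumetricImage from an array
#'
#' @param data 3-D numeric array (a 2-D matrix is promoted to a single-slice
#'   volume).
#' @param spacing voxel edge length per axis, mm; a scalar is recycled.
#' @param origin world position of the centre of voxel (0,0,0), mm.
#' @return A [VolumetricImage-class].
#' @examples
#' img <- VolumetricImage(array(seq_len(8), c(2, 2, 2)), spacing = 0.5)
#' voxelSpacing(img)
#' @export
VolumetricImage <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumetricImage", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct fluid properties
#'
#' @param rho density, kg m^-3.
#' @param mu dynamic viscosity, Pa s.
#' @export
FluidProps <- function(rho, mu) new("FluidProps", rho = rho, mu = mu)

#' Working-fluid presets
#'
#' `"blood"` (rho = 1030 kg m^-3, mu = 0.004 Pa s), `"air"`
#' (rho = 1.18415 kg m^-3, mu = 1.85508e-5 Pa s) and `"unit"`
#' (rho = mu = 1).  Segmentations are insensitive to the working fluid in
#' the creeping regime; the fluid merely fills the domain.
#'
#' @param name preset name.
#' @return A [FluidProps-class].
#' @examples fluidPreset("blood")
#' @export
fluidPreset <- function(name = c("blood", "air", "unit", "water")) {
  name <- match.arg(name)
  switch(name,
    blood = FluidProps(1030, 0.004),
    air   = FluidProps(1.18415, 1.85508e-5),
    water = FluidProps(1000, 1e-3),
    unit  = FluidProps(1, 1))
}

#' @describeIn VolumetricImage the intensity array
#' @param x object to access.
#' @export
setMethod("imageData", "VolumetricImage", function(x) x@data)

#' @export
setMethod("voxelSpacing", "VolumetricImage", function(x) x@spacing)
#' @export
setMethod("imageOrigin", "VolumetricImage", function(x) x@origin)

#' @export
setMethod("voxelSpacing", "PorosityField", function(x) x@spacing)
#' @export
setMethod("imageOrigin", "PorosityField", function(x) x@origin)
#' @export
setMethod("porosity", "PorosityField", function(x) x@epsilon)
#' @export
setMethod("solidMask", "PorosityField", function(x) x@solidMask)

#' @export
setMethod("voxelSpacing", "ResistanceField", function(x) x@spacing)
#' @export
setMethod("imageOrigin", "ResistanceField", function(x) x@origin)
#' @export
setMethod("viscousResistance", "ResistanceField", function(x) x@Pv)
#' @export
setMethod("inertialResistance", "ResistanceField", function(x) x@Pi)

#' @export
setMethod("voxelSpacing", "FlowSolution", function(x) x@spacing)
#' @export
setMethod("imageOrigin", "FlowSolution", function(x) x@origin)

#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)
#' @export
setMethod("meshTriangles", "SurfaceMesh", function(x) x@triangles)
#' @export
setMethod("isWatertight", "SurfaceMesh", function(x) x@watertight)

#' @export
setMethod("sweepTable", "IsoSweep", function(x) x@table)
#' @export
setMethod("sweepTable", "IndicatorCurve", function(x) x@table)

dimOrEmpty <- function(a) paste(dim(a), collapse = " x ")

setMethod("show", "VolumetricImage", function(object) {
  cat("VolumetricImage:", dimOrEmpty(object@data), "voxels\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      "  origin (mm):", paste(signif(object@origin, 4), collapse = ", "), "\n")
  cat("  intensity range:", paste(signif(range(object@data), 5),
                                  collapse = " .. "), "\n")
})

setMethod("show", "PorosityField", function(object) {
  cat("PorosityField:", dimOrEmpty(object@epsilon), "voxels\n")
  cat("  fluid voxels:", sum(!object@solidMask),
      " solid voxels:", sum(object@solidMask), "\n")
  cat("  epsMin:", object@epsMin, "\n")
})

setMethod("show", "ResistanceField", function(object) {
  cat("ResistanceField:", dimOrEmpty(object@Pv), "voxels\n")
  cat("  Pv range (kg m^-3 s^-1):",
      paste(signif(range(object@Pv), 4), collapse = " .. "),
      "  d (m):", signif(object@d, 4), "\n")
})

setMethod("show", "FlowDomain", function(object) {
  cat("FlowDomain:", dimOrEmpty(object@fluidMask), "cells,",
      sum(object@fluidMask), "fluid\n")
  cat("  inlets:", length(object@inlets), " outlets:",
      length(object@outlets), "\n")
})

setMethod("show", "FlowSolution", function(object) {
  cat("FlowSolution:", dimOrEmpty(object@pressure), "cells\n")
  cat("  max speed (m s^-1):", signif(max(object@speed), 4), "\n")
  if (!is.null(object@info$relResidual))
    cat("  relative residual:", signif(object@info$relResidual, 3), "\n")
})

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles,", object@ncomp, "component(s)\n")
  cat("  watertight:", object@watertight,
      " area (mm^2):", signif(meshArea(object), 5),
      " volume (mm^3):", signif(meshVolume(object), 5), "\n")
})

setMethod("show", "IsoSweep", function(object) {
  cat("IsoSweep over", nrow(object@table), "iso-values in [",
      signif(min(object@table$iso), 3), ",",
      signif(max(object@table$iso), 3), "] m s^-1\n")
})

setMethod("show", "IndicatorCurve", function(object) {
  cat("IndicatorCurve:", nrow(object@table), "points; iso0 =",
      signif(object@iso0, 3), "m s^-1; R0 =", signif(object@R0, 4),
      "mm; r0 =", signif(object@r0, 4), "mm\n")
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: iso =", signif(object@chosenIso, 4),
      "m s^-1 (", object@method, ")\n")
})

setMethod("show", "ContrastReport", function(object) {
  cat("ContrastReport: CNR =", signif(object@cnr, 4),
      " SNR =", signif(object@snr, 4), "\n")
  cat("  object mean/sd:", signif(object@meanObject, 5), "/",
      signif(object@sdObject, 5), "\n")
  cat("  background mean/sd:", signif(object@meanBackground, 5), "/",
      signif(object@sdBackground, 5), "\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult: A =", signif(object@A, 6), " B =", signif(object@B, 3),
      " rms =", signif(object@rmsResidual, 3), " (n =", object@n, ")\n")
})
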