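## Central S4 containers.  All physics is SI internally (metres, Pa, kg);
## image-space lengths (spacing, origin, mesh coordinates) are millimetres.

#' VolumetricImage: a 3-D scalar intensity grid with geometry
#'
#' Holds a greyscale volume (e.g. CT in Hounsfield units) together with the
#' per-axis voxel edge length and the world position of the centre of voxel
#' (0,0,0).  Voxel indices are 0-based in the world-coordinate convention:
#' world = origin + spacing * index (voxel-centre convention).
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing numeric(3), voxel edge length per axis, mm, all > 0.
#' @slot origin numeric(3), world position of the centre of voxel (0,0,0), mm.
#' @export
setClass("VolumetricImage",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VolumetricImage", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data values must be finite")
  if (length(msg)) msg else TRUE
})

#' PorosityField: per-voxel fluid fraction with solid mask
#'
#' @slot epsilon 3-D array, porosity in [0, 1].
#' @slot solidMask logical 3-D array; TRUE marks voxels removed from the flow
#'   domain (porosity at or below the solidification cutoff, or outside the
#'   candidate mask).
#' @slot spacing numeric(3), mm.
#' @slot origin numeric(3), mm.
#' @slot epsMin porosity cutoff used by [solidify()]; NA before solidification.
#' @export
setClass("PorosityField",
  representation(epsilon = "array", solidMask = "array", spacing = "numeric",
                 origin = "numeric", epsMin = "numeric"),
  prototype(epsMin = NA_real_))

setValidity("PorosityField", function(object) {
  msg <- character()
  if (length(dim(object@epsilon)) != 3L)
    msg <- c(msg, "epsilon must be a 3-D array")
  rng <- range(object@epsilon)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "epsilon must lie in [0, 1]")
  if (!identical(dim(object@epsilon), dim(object@solidMask)))
    msg <- c(msg, "solidMask dimensions must match epsilon")
  if (!is.logical(object@solidMask))
    msg <- c(msg, "solidMask must be logical")
  if (!is.na(object@epsMin) &&
      any(object@epsilon <= object@epsMin & !object@solidMask))
    msg <- c(msg, "solidMask must cover all voxels with epsilon <= epsMin")
  if (length(msg)) msg else TRUE
})

#' ResistanceField: per-voxel porous resistance coefficients
#'
#' Viscous resistance P_v (kg m^-3 s^-1) and inertial resistance coefficient
#' P_i (kg m^-4, zero by default: the calibrated inertial constant vanishes
#' in the creeping regime).
#'
#' @slot Pv 3-D array, viscous resistance, kg m^-3 s^-1, >= 0.
#' @slot Pi 3-D array, inertial resistance coefficient, kg m^-4.
#' @slot d voxel edge length used in the resistance law, metres.
#' @slot spacing numeric(3), mm.
#' @slot origin numeric(3), mm.
#' @export
setClass("ResistanceField",
  representation(Pv = "array", Pi = "array", d = "numeric",
                 spacing = "numeric", origin = "numeric"))

setValidity("ResistanceField", function(object) {
  msg <- character()
  if (any(object@Pv < 0)) msg <- c(msg, "Pv must be non-negative")
  if (!identical(dim(object@Pv), dim(object@Pi)))
    msg <- c(msg, "Pi dimensions must match Pv")
  if (length(object@d) != 1L || !is.finite(object@d) || object@d <= 0)
    msg <- c(msg, "d must be a single positive voxel edge length in metres")
  if (length(msg)) msg else TRUE
})

#' FluidProps: density and dynamic viscosity of the working fluid
#'
#' @slot rho density, kg m^-3.
#' @slot mu dynamic viscosity, Pa s.
#' @export
setClass("FluidProps", representation(rho = "numeric", mu = "numeric"))

setValidity("FluidProps", function(object) {
  if (length(object@rho) != 1L || length(object@mu) != 1L ||
      !is.finite(object@rho) || !is.finite(object@mu) ||
      object@rho <= 0 || object@mu <= 0)
    "rho and mu must be single positive finite values" else TRUE
})

#' FlowDomain: solidified voxel domain with boundary annotations
#'
#' Exterior faces of the fluid region are classified as inlet, outlet,
#' symmetry or (default) no-slip wall.  Inlet/outlet specs select faces by a
#' bounding-box side plus an optional in-plane mask.
#'
#' @slot fluidMask logical 3-D array; TRUE for cells in the flow domain.
#' @slot resistance a [ResistanceField-class].
#' @slot spacing numeric(3), mm (isotropic required by the solver).
#' @slot origin numeric(3), mm.
#' @slot inlets list of boundary specs (side, optional mask, optional speed
#'   or profile function).
#' @slot outlets list of boundary specs.
#' @slot symmetrySides character vector of box sides treated as shear-free
#'   symmetry planes ("x-", "x+", "y-", "y+", "z-", "z+").
#' @export
setClass("FlowDomain",
  representation(fluidMask = "array", resistance = "ResistanceField",
                 spacing = "numeric", origin = "numeric",
                 inlets = "list", outlets = "list",
                 symmetrySides = "character"))

setValidity("FlowDomain", function(object) {
  msg <- character()
  if (!is.logical(object@fluidMask))
    msg <- c(msg, "fluidMask must be logical")
  if (!identical(dim(object@fluidMask), dim(object@resistance@Pv)))
    msg <- c(msg, "fluidMask dimensions must match resistance field")
  if (length(object@inlets) == 0L) msg <- c(msg, "inlet set must be non-empty")
  if (length(object@outlets) == 0L) msg <- c(msg, "outlet set must be non-empty")
  bad <- setdiff(object@symmetrySides, c("x-", "x+", "y-", "y+", "z-", "z+"))
  if (length(bad)) msg <- c(msg, "invalid symmetry side labels")
  if (length(msg)) msg else TRUE
})

#' FlowSolution: staggered-face velocities and cell pressures
#'
#' Superficial velocity components live on cell faces (marker-and-cell
#' layout): u on (nx+1, ny, nz), v on (nx, ny+1, nz), w on (nx, ny, nz+1).
#' Pressure and the derived speed field are cell-centred.
#'
#' @slot u,v,w numeric arrays of face-normal superficial velocities, m s^-1.
#' @slot pressure cell-centred pressure, Pa (NA outside the fluid region).
#' @slot speed cell-centred |v_s|, m s^-1 (zero outside the fluid region).
#' @slot fluidMask logical 3-D array.
#' @slot spacing numeric(3), mm.
#' @slot origin numeric(3), mm.
#' @slot info list: convergence and mass-balance diagnostics.
#' @export
setClass("FlowSolution",
  representation(u = "array", v = "array", w = "array",
                 pressure = "array", speed = "array", fluidMask = "array",
                 spacing = "numeric", origin = "numeric", info = "list"))

#' SurfaceMesh: a triangulated surface in world coordinates (mm)
#'
#' @slot vertices n x 3 numeric matrix, mm.
#' @slot triangles m x 3 integer matrix of 1-based vertex indices, ordered so
#'   that triangle normals point out of the enclosed region.
#' @slot watertight logical: every edge shared by exactly two triangles.
#' @slot ncomp number of connected components.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 watertight = "logical", ncomp = "integer"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@triangles) != 3L) msg <- c(msg, "triangles must be m x 3")
  if (nrow(object@triangles) &&
      (max(object@triangles) > nrow(object@vertices) ||
       min(object@triangles) < 1L))
    msg <- c(msg, "triangle indices out of range")
  if (length(msg)) msg else TRUE
})

#' IsoSweep: volume, area and component count per iso-value
#'
#' @slot table data.frame with columns iso (m s^-1, decreasing), volume
#'   (mm^3), area (mm^2), ncomp.
#' @export
setClass("IsoSweep", representation(table = "data.frame"))

#' IndicatorCurve: sphere-model radius changes across an iso sweep
#'
#' dR is the change in radius of a volume-matched model sphere, dr of an
#' area-matched one, both relative to the reference iso-value iso0.
#'
#' @slot table data.frame with columns iso, volume, area, dR, dr (mm).
#' @slot iso0 reference iso-value, m s^-1.
#' @slot R0 volume-equivalent reference radius, mm.
#' @slot r0 area-equivalent reference radius, mm.
#' @export
setClass("IndicatorCurve",
  representation(table = "data.frame", iso0 = "numeric", R0 = "numeric",
                 r0 = "numeric"))

#' SelectionResult: chosen segmentation iso-value and how it was found
#'
#' @slot chosenIso selected iso-value, m s^-1.
#' @slot method one of "plateau-inflexion", "plateau-start", "user-override".
#' @slot diagnostics list with candidate iso-values, slopes and threshold.
#' @export
setClass("SelectionResult",
  representation(chosenIso = "numeric", method = "character",
                 diagnostics = "list"))

#' ContrastReport: object/background intensity moments, CNR and SNR
#'
#' CNR = (mean_object - mean_background) / sd_background.  SNR is reported
#' under a pooled-standard-deviation convention,
#' (mean_object - mean_background) / sd_pooled, documented in the vignette.
#'
#' @slot meanObject,meanBackground,sdObject,sdBackground intensity moments.
#' @slot cnr,snr dimensionless ratios (NA when the defining sd is zero).
#' @export
setClass("ContrastReport",
  representation(meanObject = "numeric", meanBackground = "numeric",
                 sdObject = "numeric", sdBackground = "numeric",
                 cnr = "numeric", snr = "numeric"))

#' FitResult: fitted porous-model constants
#'
#' Least-squares fit of the friction-factor relation f_b = A / Re_b + B.
#'
#' @slot A viscous constant.
#' @slot B inertial constant.
#' @slot rmsResidual root-mean-square residual of the fit in f_b units.
#' @slot n number of friction points used.
#' @export
setClass("FitResult",
  representation(A = "numeric", B = "numeric", rmsResidual = "numeric",
                 n = "integer"))
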