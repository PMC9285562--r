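#' Convert image intensity to porosity
#'
#' The linear partial-volume model: a voxel straddling the fluid-tissue
#' boundary has intensity I_v = I_s + eps * (I_f - I_s), so
#' eps = (I_v - I_s) / (I_f - I_s), clipped to [0, 1].  Either orientation
#' of the reference intensities is allowed (bright fluid for contrast CT
#' angiography, dark fluid for airways).  Voxels outside the candidate mask
#' are assigned eps = 0 and marked solid.
#'
#' @param img a [VolumetricImage-class].
#' @param If intensity of pure fluid.
#' @param Is intensity of pure solid (tissue); `If != Is`.
#' @param candidateMask logical array from [coarseThreshold()]; `NULL`
#'   keeps every voxel.
#' @return A [PorosityField-class] (not yet solidified: `epsMin` is NA and
#'   the solid mask only covers voxels excluded by the candidate mask).
#' @examples
#' img <- VolumetricImage(array(c(0, 50, 100), c(3, 1, 1)))
#' porosity(porosityFromIntensity(img, If = 100, Is = 0))
#' @export
porosityFromIntensity <- function(img, If, Is, candidateMask = NULL) {
  assertThat(is.finite(If) && is.finite(Is) && If != Is,
             "fluid and solid reference intensities must differ")
  eps <- clamp((img@data - Is) / (If - Is), 0, 1)
  solid <- array(FALSE, dim(eps))
  if (!is.null(candidateMask)) {
    assertThat(identical(dim(candidateMask), dim(eps)),
               "candidateMask dimensions must match the image")
    eps[!candidateMask] <- 0
    solid[!candidateMask] <- TRUE
  }
  new("PorosityField", epsilon = eps, solidMask = solid,
      spacing = img@spacing, origin = img@origin, epsMin = NA_real_)
}

#' Solidify low-porosity voxels
#'
#' The shrunken-voxel resistance is singular as porosity tends to zero, so
#' voxels with porosity at or below `epsMin` (closed inequality) are
#' declared entirely solid and removed from the computational domain.
#'
#' @param pf a [PorosityField-class].
#' @param epsMin porosity cutoff in (0, 1); default 0.1.
#' @return The solidified [PorosityField-class].
#' @export
solidify <- function(pf, epsMin = 0.1) {
  assertThat(epsMin > 0 && epsMin < 1, "epsMin must lie in (0, 1)")
  solid <- pf@solidMask | pf@epsilon <= epsMin
  new("PorosityField", epsilon = pf@epsilon, solidMask = solid,
      spacing = pf@spacing, origin = pf@origin, epsMin = epsMin)
}

#' Shrunken-voxel viscous resistance field
#'
#' The shrunken-voxel model splits each boundary voxel into opposing solid
#' and fluid slabs; relative to a fully fluid reference voxel the calibrated
#' viscous resistance is
#' \deqn{P_v = 3 \frac{(1-\varepsilon)^2}{\varepsilon^3 d^2} \mu}
#' with d the isotropic voxel edge length in metres.  P_v = 0 where
#' eps = 1 and on solidified voxels (which are excluded from the flow
#' domain anyway).
#'
#' @param pf a solidified [PorosityField-class] with isotropic spacing.
#' @param fluid a [FluidProps-class].
#' @return A [ResistanceField-class] (inertial part zero: the calibrated
#'   inertial constant vanishes in the creeping regime).
#' @examples
#' pf <- new("PorosityField", epsilon = array(0.5, c(1, 1, 1)),
#'           solidMask = array(FALSE, c(1, 1, 1)), spacing = rep(1, 3),
#'           origin = rep(0, 3), epsMin = 0.1)
#' viscousResistance(shrunkenViscousResistance(pf, FluidProps(1000, 1e-3)))
#' @export
shrunkenViscousResistance <- function(pf, fluid) {
  assertThat(!is.na(pf@epsMin), "porosity field must be solidified first")
  h <- isotropicSpacing(pf@spacing, "shrunken-voxel resistance")
  d <- h * 1e-3  # mm -> m
  eps <- pf@epsilon
  Pv <- array(0, dim(eps))
  fl <- !pf@solidMask
  Pv[fl] <- 3 * (1 - eps[fl])^2 / (eps[fl]^3 * d^2) * fluid@mu
  new("ResistanceField", Pv = Pv, Pi = array(0, dim(eps)), d = d,
      spacing = pf@spacing, origin = pf@origin)
}

#' Packed-bed (Blake-Kozeny) viscous resistance
#'
#' Comparison-mode scalar resistance for a granular packed bed of spherical
#' particles of diameter `Dp`:
#' \deqn{P_v = 150 \frac{(1-\varepsilon)^2}{\varepsilon^3} \frac{\mu}{D_p^2}}
#'
#' @param eps porosity, strictly inside (0, 1).
#' @param fluid a [FluidProps-class].
#' @param Dp particle diameter, metres.
#' @return Viscous resistance, kg m^-3 s^-1.
#' @export
packedBedViscousResistance <- function(eps, fluid, Dp) {
  assertThat(all(eps > 0 & eps < 1),
             "packed-bed resistance requires 0 < eps < 1")
  assertThat(Dp > 0, "Dp must be positive")
  150 * (1 - eps)^2 / eps^3 * fluid@mu / Dp^2
}

#' Blake number diagnostic
#'
#' A porous-media Reynolds analogue quantifying viscous versus inertial
#' dominance per voxel:
#' \deqn{Bl = \frac{\rho u d}{\mu} \frac{\varepsilon}{1-\varepsilon}}
#' Vectorised over `speed` and `eps`; returns `Inf` where eps = 1.
#'
#' @param speed physical flow speed u, m s^-1.
#' @param eps porosity.
#' @param d voxel edge length, metres.
#' @param fluid a [FluidProps-class].
#' @return Blake number (dimensionless).
#' @export
blakeNumber <- function(speed, eps, d, fluid) {
  assertThat(all(eps > 0 & eps <= 1), "Blake number requires 0 < eps <= 1")
  bl <- fluid@rho * speed * d / fluid@mu * eps / (1 - eps)
  bl[eps == 1] <- Inf
  bl
}
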