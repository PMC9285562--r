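#' Extract a velocity-magnitude iso-surface
#'
#' Marching-tetrahedra tessellation (linear edge interpolation) of the
#' level set `field >= iso`, in world coordinates (mm).  The grid is padded
#' with `padValue` so that level sets touching the domain boundary close
#' into watertight surfaces.  By default the largest connected component
#' (by enclosed volume) is retained; satellite blobs from residual noise
#' are thereby discarded.
#'
#' @param field 3-D array (typically the speed field, m s^-1).
#' @param iso iso-value, must be positive and below the field maximum.
#' @param spacing voxel spacing, mm (length 3 or scalar).
#' @param origin world position of voxel (0,0,0), mm.
#' @param keepLargestOnly retain only the largest connected component.
#' @param padValue value used for the closing pad layer.
#' @return A [SurfaceMesh-class].
#' @export
extractIsosurface <- function(field, iso, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0), keepLargestOnly = TRUE,
                              padValue = 0) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  assertThat(iso > 0 && iso < max(field),
             "iso must lie in (0, max(field))")
  d <- dim(field)
  padded <- array(padValue, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- field
  res <- .marchingTetrahedra(as.numeric(padded), dim(padded), iso,
                             as.numeric(spacing),
                             as.numeric(origin - spacing))
  mesh <- SurfaceMesh(res$vertices, res$triangles)
  if (keepLargestOnly) mesh <- largestComponent(mesh)
  mesh
}

#' Sweep iso-surfaces over a list of iso-values
#'
#' For each iso-value, records the total enclosed volume (mm^3), total
#' surface area (mm^2) and connected-component count of the level set
#' (all components, so noise shows up in the counts).
#'
#' @param field 3-D speed array, m s^-1.
#' @param isoValues positive iso-values; stored in decreasing order.
#' @param spacing,origin grid geometry, mm.
#' @return An [IsoSweep-class].
#' @export
isoSweep <- function(field, isoValues, spacing = c(1, 1, 1),
                     origin = c(0, 0, 0)) {
  assertThat(all(isoValues > 0), "iso-values must be positive")
  isoValues <- sort(unique(isoValues), decreasing = TRUE)
  rows <- lapply(isoValues, function(iso) {
    if (iso >= max(field))
      return(data.frame(iso = iso, volume = 0, area = 0, ncomp = 0L))
    mesh <- extractIsosurface(field, iso, spacing, origin,
                              keepLargestOnly = FALSE)
    data.frame(iso = iso, volume = meshVolume(mesh), area = meshArea(mesh),
               ncomp = mesh@ncomp)
  })
  new("IsoSweep", table = do.call(rbind, rows))
}

#' Default iso-value sweep
#'
#' 33 log-spaced values over `range` (default 1e-14 to 1e-6 m/s) plus
#' the reference iso-value `iso0`.
#'
#' @param iso0 reference iso-value to include, m s^-1.
#' @param range sweep range, m s^-1.
#' @param n number of log-spaced values.
#' @return Decreasing vector of iso-values.
#' @export
defaultIsoValues <- function(iso0 = NULL, range = c(1e-14, 1e-6), n = 33L) {
  vals <- 10^seq(log10(range[1]), log10(range[2]), length.out = n)
  sort(unique(c(vals, iso0)), decreasing = TRUE)
}

#' Spherical-model indicator curve
#'
#' Equates the segmented volume and area at each iso-value to those of a
#' model sphere.  With reference radii at iso0,
#' R0 = (3 V(iso0) / 4 pi)^(1/3) and r0 = sqrt(A(iso0) / 2 pi), the
#' indicators are dR(iso) = (3 V(iso) / 4 pi)^(1/3) - R0 and
#' dr(iso) = sqrt(A(iso) / 2 pi) - r0.  (The area model uses the constant
#' 2 pi; it rescales r0 and dr jointly and does not move plateau or
#' inflexion locations.)
#'
#' @param sweep an [IsoSweep-class] containing `iso0`.
#' @param iso0 reference iso-value; by convention one order of magnitude
#'   below the inlet speed for compact objects, or the inlet speed itself
#'   for complex/airway-like objects.
#' @return An [IndicatorCurve-class].
#' @export
indicatorCurve <- function(sweep, iso0) {
  tb <- sweep@table
  i0 <- which(abs(tb$iso - iso0) <= 1e-12 * iso0)
  assertThat(length(i0) == 1L, "iso0 must be one of the sweep iso-values")
  assertThat(tb$volume[i0] > 0 && tb$area[i0] > 0,
             "zero volume or area at iso0; choose a lower reference iso")
  R0 <- (3 * tb$volume[i0] / (4 * pi))^(1 / 3)
  r0 <- sqrt(tb$area[i0] / (2 * pi))
  tb$dR <- (3 * tb$volume / (4 * pi))^(1 / 3) - R0
  tb$dr <- sqrt(tb$area / (2 * pi)) - r0
  new("IndicatorCurve", table = tb, iso0 = iso0, R0 = R0, r0 = r0)
}

#' Select the segmentation iso-value from an indicator curve
#'
#' Scans the indicator (dR by default, dr optionally: a slightly better
#' indicator for scroll-like geometries) against log10(iso).  Plateau
#' segments are those whose absolute slope is below `slopeFraction` of the
#' sweep's maximum slope.  If the plateau is followed (towards lower
#' iso-values) by a renewed steep change, the plateau end at that
#' inflexion is returned; otherwise the plateau start.  A user override is
#' honoured and recorded.
#'
#' @param curve an [IndicatorCurve-class] with at least 8 points.
#' @param indicator `"dR"` (volume-based) or `"dr"` (area-based).
#' @param slopeFraction plateau slope threshold as a fraction of the
#'   maximum slope.
#' @param userIso optional manual override, m s^-1.
#' @return A [SelectionResult-class].
#' @export
selectIso <- function(curve, indicator = c("dR", "dr"),
                      slopeFraction = 0.05, userIso = NULL) {
  indicator <- match.arg(indicator)
  tb <- curve@table[order(curve@table$iso, decreasing = TRUE), ]
  if (!is.null(userIso))
    return(new("SelectionResult", chosenIso = userIso,
               method = "user-override", diagnostics = list()))
  assertThat(nrow(tb) >= 8L, "need at least 8 sweep points")
  x <- log10(tb$iso)
  y <- tb[[indicator]]
  s <- abs(diff(y) / diff(x))       # slope per segment, high iso -> low iso
  smax <- max(s)
  assertThat(smax > 0, "indicator curve is entirely flat; no plateau bounds")
  plateau <- s < slopeFraction * smax
  if (!any(plateau))
    stop("no plateau found in the indicator curve; ",
         "choose the iso-value manually (userIso)", call. = FALSE)
  ## maximal runs of plateau segments
  r <- rle(plateau)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, len = r$lengths,
                     val = r$values)
  runs <- runs[runs$val, , drop = FALSE]
  ## longest run; ties resolved towards lower iso (later run)
  best <- runs[order(-runs$len, -runs$start), ][1, ]
  ## segment i spans points i (higher iso) .. i+1 (lower iso)
  lowPoint <- best$end + 1L      # lowest-iso point of the plateau
  highPoint <- best$start        # highest-iso point of the plateau
  upturn <- best$end < length(s) && any(s[(best$end + 1L):length(s)] >=
                                          slopeFraction * smax)
  if (upturn) {
    chosen <- tb$iso[lowPoint]; method <- "plateau-inflexion"
  } else {
    chosen <- tb$iso[highPoint]; method <- "plateau-start"
  }
  new("SelectionResult", chosenIso = chosen, method = method,
      diagnostics = list(
        slopes = s, threshold = slopeFraction * smax, indicator = indicator,
        plateauStartIso = tb$iso[highPoint], plateauEndIso = tb$iso[lowPoint]))
}

#' Cloud-to-mesh distance statistics
#'
#' For every vertex of the test surface, the unsigned distance to the
#' nearest point on any reference triangle; statistics are normalised by
#' the original in-plane pixel size (so values are in voxel units, and the
#' sub-voxel accuracy criterion reads "mean and sd below one").
#'
#' @param test a [SurfaceMesh-class] whose vertices form the cloud.
#' @param reference the reference [SurfaceMesh-class].
#' @param pixelSizeMm normalisation length: the scanning in-plane pixel
#'   size of the original image, mm.
#' @return Named vector: `mean`, `max`, `sd` (voxel units) and `n`.
#' @export
cloudToMeshDistance <- function(test, reference, pixelSizeMm = 1) {
  assertThat(nrow(test@vertices) > 0, "test mesh is empty")
  assertThat(nrow(reference@triangles) > 0, "reference mesh is empty")
  d <- .pointMeshDistances(test@vertices, reference@vertices,
                           reference@triangles) / pixelSizeMm
  c(mean = mean(d), max = max(d), sd = sd(d), n = length(d))
}
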