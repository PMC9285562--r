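#' Crop a volume to a region of interest
#'
#' ROI boxes use 0-based, half-open index bounds per axis.  The origin is
#' shifted so that world coordinates of the retained voxels are unchanged.
#'
#' @param img a [VolumetricImage-class].
#' @param lower,upper integer vectors of length 3: 0-based lower (inclusive)
#'   and upper (exclusive) index bounds.
#' @return The cropped [VolumetricImage-class].
#' @examples
#' img <- VolumetricImage(array(1:64, c(4, 4, 4)))
#' cropVolume(img, c(1, 1, 1), c(3, 3, 3))
#' @export
cropVolume <- function(img, lower, upper) {
  d <- dim(img@data)
  lower <- as.integer(lower); upper <- as.integer(upper)
  assertThat(length(lower) == 3L && length(upper) == 3L,
             "lower/upper must have length 3")
  assertThat(all(lower < upper), "ROI requires lower < upper on every axis")
  assertThat(all(lower >= 0L) && all(upper <= d),
             "ROI outside image extent")
  out <- img@data[(lower[1] + 1L):upper[1],
                  (lower[2] + 1L):upper[2],
                  (lower[3] + 1L):upper[3], drop = FALSE]
  VolumetricImage(out, spacing = img@spacing,
                  origin = img@origin + img@spacing * lower)
}

#' Resample a volume to isotropic spacing by trilinear interpolation
#'
#' New voxel centres are placed on an isotropic grid starting at the input
#' origin and covering the input extent.  Sampling outside the source grid
#' is clamped to the edge voxel (no background intensity is invented).
#' Trilinear interpolation reproduces affine intensity fields exactly and
#' never produces values outside the input range.
#'
#' @param img a [VolumetricImage-class].
#' @param targetSpacing isotropic target voxel edge length, mm.
#' @return A [VolumetricImage-class] with spacing
#'   `c(targetSpacing, targetSpacing, targetSpacing)`.
#' @export
resampleIsotropic <- function(img, targetSpacing) {
  assertThat(is.numeric(targetSpacing) && length(targetSpacing) == 1L &&
             targetSpacing > 0, "targetSpacing must be a single positive value")
  d <- dim(img@data); sp <- img@spacing
  extent <- (d - 1L) * sp  # centre-to-centre extent per axis
  assertThat(all(targetSpacing <= extent + sp),
             "targetSpacing larger than the image extent")
  nout <- pmax(1L, as.integer(floor(extent / targetSpacing)) + 1L)
  ## fractional source indices (0-based) of the new voxel centres
  ax <- lapply(1:3, function(k) (seq_len(nout[k]) - 1) * targetSpacing / sp[k])
  out <- trilinearSample(img@data, ax[[1]], ax[[2]], ax[[3]])
  VolumetricImage(array(out, nout), spacing = rep(targetSpacing, 3L),
                  origin = img@origin)
}

## Sample a 3-D array at the tensor grid of fractional 0-based indices
## (ix, iy, iz), clamped to the edge.  Returns an array of
## length(ix) x length(iy) x length(iz).
trilinearSample <- function(a, ix, iy, iz) {
  d <- dim(a)
  lo <- function(t, n) clamp(floor(t), 0, n - 1L)
  x0 <- lo(ix, d[1]); y0 <- lo(iy, d[2]); z0 <- lo(iz, d[3])
  x1 <- pmin(x0 + 1, d[1] - 1L); y1 <- pmin(y0 + 1, d[2] - 1L)
  z1 <- pmin(z0 + 1, d[3] - 1L)
  fx <- clamp(ix - x0, 0, 1); fy <- clamp(iy - y0, 0, 1)
  fz <- clamp(iz - z0, 0, 1)
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  ## broadcast helper arrays
  FX <- array(fx, c(nx, ny, nz))
  FY <- array(rep(fy, each = nx), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  gat <- function(xs, ys, zs) {
    ii <- 1L + as.integer(xs) +
      d[1] * rep(as.integer(ys), each = nx) +
      d[1] * d[2] * rep(as.integer(zs), each = nx * ny)
    array(a[ii], c(nx, ny, nz))
  }
  c000 <- gat(x0, y0, z0); c100 <- gat(x1, y0, z0)
  c010 <- gat(x0, y1, z0); c110 <- gat(x1, y1, z0)
  c001 <- gat(x0, y0, z1); c101 <- gat(x1, y0, z1)
  c011 <- gat(x0, y1, z1); c111 <- gat(x1, y1, z1)
  (((c000 * (1 - FX) + c100 * FX) * (1 - FY) +
    (c010 * (1 - FX) + c110 * FX) * FY) * (1 - FZ) +
   ((c001 * (1 - FX) + c101 * FX) * (1 - FY) +
    (c011 * (1 - FX) + c111 * FX) * FY) * FZ)
}

#' Coarse intensity thresholding
#'
#' Returns the candidate mask of voxels whose intensity lies in the closed
#' interval `[imin, imax]`; voxels outside the range are discarded from all
#' subsequent processing.
#'
#' @param img a [VolumetricImage-class].
#' @param imin,imax inclusive intensity bounds, `imin < imax`.
#' @return A logical 3-D array.
#' @export
coarseThreshold <- function(img, imin, imax) {
  assertThat(is.finite(imin) && is.finite(imax) && imin < imax,
             "coarse range requires imin < imax")
  img@data >= imin & img@data <= imax
}

#' Object/background contrast diagnostics
#'
#' Computes the object and background intensity means and standard
#' deviations (population moments over the masked voxels), the
#' contrast-to-noise ratio
#' CNR = (mean_object - mean_background) / sd_background, and a
#' signal-to-noise ratio under the pooled-sd convention
#' SNR = (mean_object - mean_background) / sd_pooled with
#' sd_pooled^2 = (sd_object^2 + sd_background^2) / 2.
#'
#' @param img a [VolumetricImage-class].
#' @param objectMask,backgroundMask non-empty, disjoint logical arrays
#'   matching the image dimensions.
#' @return A [ContrastReport-class].  `cnr` is NA (with a warning) when the
#'   background variance is zero.
#' @export
contrastMetrics <- function(img, objectMask, backgroundMask) {
  assertThat(any(objectMask), "object mask is empty")
  assertThat(any(backgroundMask), "background mask is empty")
  assertThat(!any(objectMask & backgroundMask),
             "object and background masks must be disjoint")
  ob <- img@data[objectMask]; bg <- img@data[backgroundMask]
  mo <- mean(ob); mb <- mean(bg)
  ## population standard deviations: moments of the voxel set itself
  so <- sqrt(mean((ob - mo)^2))
  sb <- sqrt(mean((bg - mb)^2))
  cnr <- if (sb > 0) (mo - mb) / sb else {
    warning("zero-variance background: CNR undefined"); NA_real_ }
  sp <- sqrt((so^2 + sb^2) / 2)
  snr <- if (sp > 0) (mo - mb) / sp else NA_real_
  new("ContrastReport", meanObject = mo, meanBackground = mb,
      sdObject = so, sdBackground = sb, cnr = cnr, snr = snr)
}
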