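#' World coordinates of voxel indices
#'
#' Voxel-centre convention: world = origin + spacing * index with 0-based
#' indices.
#'
#' @param x an object with spacing and origin ([VolumetricImage-class],
#'   [PorosityField-class], ...).
#' @param index n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates, mm.
#' @examples
#' img <- VolumetricImage(array(0, c(4, 4, 4)), spacing = 0.5,
#'                        origin = c(1, 2, 3))
#' worldCoordinates(img, c(2, 0, 1))
#' @export
worldCoordinates <- function(x, index) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  sweep(sweep(index, 2, voxelSpacing(x), "*"), 2, imageOrigin(x), "+")
}

## clamp values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## stopifnot-with-message helper
assertThat <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## spacing must be isotropic (within floating tolerance); returns the common
## edge length
isotropicSpacing <- function(spacing, what = "field") {
  if (diff(range(spacing)) > 1e-9 * max(spacing))
    stop(what, " requires isotropic spacing; resample first (resampleIsotropic)",
         call. = FALSE)
  spacing[1]
}

## seeded RNG scope: fixed, documented generator so phantoms are reproducible
## across platforms
withPhantomSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
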