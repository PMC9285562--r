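## Ground-truthed synthetic phantoms.  Analytic solids (exact signed
## distance functions) are voxelized with a stratified sub-sampling
## partial-volume estimate, rendered to intensity by the linear mixing
## model, optionally blurred along z (slice-thickness smearing) and
## corrupted with seeded Gaussian noise and speckle blobs.

sdfSphere <- function(p, center, radius)
  sqrt(rowSums(sweep(p, 2, center)^2)) - radius

sdfCapsule <- function(p, p1, p2, radius) {
  ab <- p2 - p1
  ap <- sweep(p, 2, p1)
  t <- clamp(as.numeric(ap %*% ab) / sum(ab^2), 0, 1)
  q <- ap - outer(t, ab)
  sqrt(rowSums(q^2)) - radius
}

sdfTorus <- function(p, center, majorRadius, minorRadius) {
  q <- sweep(p, 2, center)
  sqrt((sqrt(q[, 1]^2 + q[, 2]^2) - majorRadius)^2 + q[, 3]^2) - minorRadius
}

## signed distance of the union of primitives (negative inside the fluid)
phantomSdf <- function(primitives) {
  force(primitives)
  function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    vals <- vapply(primitives, function(pr) {
      switch(pr$type,
        sphere = sdfSphere(p, pr$center, pr$radius),
        capsule = sdfCapsule(p, pr$p1, pr$p2, pr$radius),
        torus = sdfTorus(p, pr$center, pr$majorRadius, pr$minorRadius),
        stop("unknown primitive type: ", pr$type))
    }, numeric(nrow(p)))
    if (length(primitives) == 1L) as.numeric(vals) else
      do.call(pmin, as.data.frame(vals))
  }
}

#' Phantom specification
#'
#' @param dims grid size, voxels (length 3 or scalar).
#' @param primitives list of analytic solids; each a list with `type`
#'   (`"sphere"`, `"capsule"`, `"torus"`) and its geometry in mm
#'   (`center`/`radius`, `p1`/`p2`/`radius`,
#'   `center`/`majorRadius`/`minorRadius`).
#' @param spacing voxel spacing, mm (anisotropic allowed).
#' @param If,Is pure-fluid and pure-solid intensities (either orientation:
#'   bright fluid emulates contrast CT angiography, dark fluid an airway).
#' @param noiseSd additive Gaussian noise standard deviation (intensity).
#' @param speckleCount number of speckle blobs (small high/low intensity
#'   spheres emulating unwanted voxels in poor-quality data).
#' @param speckleRadiusMm,speckleIntensity blob radius and added intensity.
#' @param sliceBlurSigmaZ Gaussian blur sd along z, mm (slice-thickness
#'   smearing); 0 disables.
#' @param seed integer RNG seed; fixed seed gives bitwise-identical output.
#' @return Phantom spec (list).
#' @export
phantomSpec <- function(dims, primitives, spacing = 0.1, If = 200, Is = 0,
                        noiseSd = 0, speckleCount = 0L,
                        speckleRadiusMm = 0.2, speckleIntensity = NULL,
                        sliceBlurSigmaZ = 0, seed = 1L) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  assertThat(If != Is, "If and Is must differ")
  if (is.null(speckleIntensity)) speckleIntensity <- (If - Is) * 0.8
  list(dims = as.integer(dims), primitives = primitives,
       spacing = as.numeric(spacing), If = If, Is = Is, noiseSd = noiseSd,
       speckleCount = as.integer(speckleCount),
       speckleRadiusMm = speckleRadiusMm,
       speckleIntensity = speckleIntensity,
       sliceBlurSigmaZ = sliceBlurSigmaZ, seed = as.integer(seed))
}

#' Partial-volume voxelization of a phantom
#'
#' Estimates the per-voxel fluid fraction by `n^3` stratified sub-samples
#' (sub-cell centres) of the analytic solids; voxels whose centre is more
#' than half a diagonal from the boundary are set exactly to 0 or 1.
#'
#' @param spec a [phantomSpec()].
#' @param n sub-samples per axis (>= 2).
#' @return 3-D porosity array (fluid fraction in [0, 1]).
#' @export
voxelizePartialVolume <- function(spec, n = 4L) {
  assertThat(n >= 2L, "need at least 2 sub-samples per axis")
  d <- spec$dims; sp <- spec$spacing
  sdf <- phantomSdf(spec$primitives)
  centres <- as.matrix(expand.grid(
    x = (seq_len(d[1]) - 1) * sp[1],
    y = (seq_len(d[2]) - 1) * sp[2],
    z = (seq_len(d[3]) - 1) * sp[3]))
  sc <- sdf(centres)
  halfDiag <- sqrt(sum(sp^2)) / 2
  eps <- as.numeric(sc < 0)           # exact for clearly inside/outside
  boundary <- abs(sc) <= halfDiag * 1.0001
  if (any(boundary)) {
    off1 <- ((seq_len(n) - 0.5) / n - 0.5)
    offs <- as.matrix(expand.grid(x = off1 * sp[1], y = off1 * sp[2],
                                  z = off1 * sp[3]))
    bidx <- which(boundary)
    frac <- numeric(length(bidx))
    for (s in seq_len(nrow(offs))) {
      pts <- sweep(centres[bidx, , drop = FALSE], 2, offs[s, ], "+")
      frac <- frac + (sdf(pts) < 0)
    }
    eps[bidx] <- frac / nrow(offs)
  }
  array(eps, d)
}

#' Render a porosity grid to an intensity image
#'
#' Linear partial-volume mixing I = Is + eps (If - Is), then optional
#' Gaussian slice blur along z, then seeded additive Gaussian noise and
#' speckle blobs (acquisition-order realism: blur before noise).
#'
#' @param epsGrid 3-D porosity array in [0, 1].
#' @param spec a [phantomSpec()] (supplies intensities, noise, blur, seed).
#' @return A [VolumetricImage-class].
#' @export
renderIntensity <- function(epsGrid, spec) {
  assertThat(min(epsGrid) >= 0 && max(epsGrid) <= 1,
             "porosity grid must lie in [0, 1]")
  img <- spec$Is + epsGrid * (spec$If - spec$Is)
  if (spec$sliceBlurSigmaZ > 0)
    img <- blurAlongZ(img, spec$sliceBlurSigmaZ / spec$spacing[3])
  d <- dim(img)
  withPhantomSeed(spec$seed, {
    if (spec$speckleCount > 0L) {
      sp <- spec$spacing
      for (b in seq_len(spec$speckleCount)) {
        cen <- runif(3) * (d - 1) * sp
        rad <- spec$speckleRadiusMm * runif(1, 0.5, 1.5)
        sgn <- if (runif(1) < 0.5) 1 else -1
        lo <- pmax(1L, as.integer(floor((cen - rad) / sp)) + 1L)
        hi <- pmin(d, as.integer(ceiling((cen + rad) / sp)) + 1L)
        if (any(lo > hi)) next
        sub <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                     z = lo[3]:hi[3]))
        w <- sweep(sub - 1, 2, sp, "*")
        inside <- sqrt(rowSums(sweep(w, 2, cen)^2)) <= rad
        if (any(inside)) {
          ii <- sub[inside, , drop = FALSE]
          img[cbind(ii[, 1], ii[, 2], ii[, 3])] <-
            img[cbind(ii[, 1], ii[, 2], ii[, 3])] +
            sgn * spec$speckleIntensity
        }
      }
    }
    if (spec$noiseSd > 0)
      img <- img + array(rnorm(prod(d), sd = spec$noiseSd), d)
  })
  VolumetricImage(img, spacing = spec$spacing, origin = c(0, 0, 0))
}

## 1-D Gaussian convolution along z with clamp-to-edge normalisation
blurAlongZ <- function(img, sigmaVox) {
  if (sigmaVox <= 0) return(img)
  half <- max(1L, ceiling(3 * sigmaVox))
  k <- exp(-((-half):half)^2 / (2 * sigmaVox^2))
  d <- dim(img)
  out <- array(0, d)
  wsum <- numeric(d[3])
  acc <- array(0, d)
  for (o in (-half):half) {
    zsrc <- clamp(seq_len(d[3]) + o, 1L, d[3])
    acc <- acc + img[, , zsrc, drop = FALSE] * k[o + half + 1L]
  }
  acc / sum(k)
}

## ground-truth reference mesh from the exact SDF on a refined grid
sdfMesh <- function(sdf, dims, spacing, refine = 2L) {
  rd <- (dims - 1L) * refine + 1L
  rsp <- spacing / refine
  pts <- as.matrix(expand.grid(
    x = (seq_len(rd[1]) - 1) * rsp[1],
    y = (seq_len(rd[2]) - 1) * rsp[2],
    z = (seq_len(rd[3]) - 1) * rsp[3]))
  f <- array(-sdf(pts), rd)           # positive inside the fluid
  big <- max(abs(f)) + 1
  padded <- array(-big, rd + 2L)
  padded[2:(rd[1] + 1L), 2:(rd[2] + 1L), 2:(rd[3] + 1L)] <- f
  res <- .marchingTetrahedra(as.numeric(padded), dim(padded), 0,
                             as.numeric(rsp), as.numeric(-rsp))
  SurfaceMesh(res$vertices, res$triangles)
}

#' Sphere-on-tube aneurysm phantom
#'
#' A capsule (parent vessel) spanning the grid along x, with a spherical
#' sac offset in +y, rendered with partial-volume smearing and the
#' configured blur/noise.  Ground truth is the exact union signed-distance
#' function plus a finely tessellated reference mesh.
#'
#' @param dims grid size, voxels.
#' @param tubeRadius parent-vessel radius, mm.
#' @param sacRadius aneurysm sac radius, mm (0 gives a plain tube).
#' @param neckOffset distance from the tube axis to the sac centre, mm
#'   (must leave the sac attached to the tube).
#' @param spacing voxel spacing, mm.
#' @param ... further arguments to [phantomSpec()] (If, Is, noiseSd,
#'   sliceBlurSigmaZ, speckleCount, seed, ...).
#' @return List: `image` ([VolumetricImage-class]), `spec`,
#'   `sdf` (vectorised signed distance, negative inside the fluid),
#'   `mesh` (reference [SurfaceMesh-class]), `porosity` (clean fluid
#'   fraction grid).
#' @export
aneurysmPhantom <- function(dims = 64L, tubeRadius = 0.8, sacRadius = 1.4,
                            neckOffset = NULL, spacing = 0.1, ...) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  assertThat(tubeRadius > 2 * max(spacing),
             "tube radius must exceed 2 voxels")
  extent <- (dims - 1L) * spacing
  centre <- extent / 2
  if (is.null(neckOffset)) neckOffset <- tubeRadius + 0.55 * sacRadius
  prims <- list(list(type = "capsule",
                     p1 = c(-2 * spacing[1], centre[2] - neckOffset / 2,
                            centre[3]),
                     p2 = c(extent[1] + 2 * spacing[1],
                            centre[2] - neckOffset / 2, centre[3]),
                     radius = tubeRadius))
  if (sacRadius > 0) {
    sacCentre <- c(centre[1], centre[2] - neckOffset / 2 + neckOffset,
                   centre[3])
    assertThat(neckOffset < tubeRadius + sacRadius,
               "sac disconnected from the tube")
    prims <- c(prims, list(list(type = "sphere", center = sacCentre,
                                radius = sacRadius)))
  }
  spec <- phantomSpec(dims, prims, spacing = spacing, ...)
  epsGrid <- voxelizePartialVolume(spec)
  img <- renderIntensity(epsGrid, spec)
  sdf <- phantomSdf(prims)
  list(image = img, spec = spec, sdf = sdf,
       mesh = sdfMesh(sdf, dims, spacing), porosity = epsGrid)
}

#' Parallel-channel phantom (airway-like)
#'
#' Two parallel capsules along x separated by a thin solid wall; both
#' channels meet the x- (inlet) and x+ (outlet) box sides.
#'
#' @param dims grid size, voxels.
#' @param channelRadius channel radius, mm.
#' @param wallGap centre-to-centre separation, mm; defaults to
#'   `2 * channelRadius` plus one voxel of wall.
#' @param spacing voxel spacing, mm.
#' @param ... further [phantomSpec()] arguments.
#' @return As [aneurysmPhantom()].
#' @export
channelPhantom <- function(dims = c(48L, 32L, 24L), channelRadius = 0.5,
                           wallGap = NULL, spacing = 0.1, ...) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(wallGap)) wallGap <- 2 * channelRadius + spacing[2]
  extent <- (dims - 1L) * spacing
  centre <- extent / 2
  mk <- function(y) list(type = "capsule",
                         p1 = c(-2 * spacing[1], y, centre[3]),
                         p2 = c(extent[1] + 2 * spacing[1], y, centre[3]),
                         radius = channelRadius)
  prims <- list(mk(centre[2] - wallGap / 2), mk(centre[2] + wallGap / 2))
  spec <- phantomSpec(dims, prims, spacing = spacing, ...)
  epsGrid <- voxelizePartialVolume(spec)
  img <- renderIntensity(epsGrid, spec)
  sdf <- phantomSdf(prims)
  list(image = img, spec = spec, sdf = sdf,
       mesh = sdfMesh(sdf, dims, spacing), porosity = epsGrid)
}

#' Y-bifurcation phantom
#'
#' A parent capsule from the x- side splitting into two symmetric branches
#' reaching the x+ side.
#'
#' @param dims grid size, voxels.
#' @param parentRadius,branchRadius capsule radii, mm.
#' @param branchOffset lateral half-separation of the branch ends, mm.
#' @param spacing voxel spacing, mm.
#' @param ... further [phantomSpec()] arguments.
#' @return As [aneurysmPhantom()].
#' @export
bifurcationPhantom <- function(dims = c(48L, 40L, 24L), parentRadius = 0.6,
                               branchRadius = 0.5, branchOffset = NULL,
                               spacing = 0.1, ...) {
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  extent <- (dims - 1L) * spacing
  centre <- extent / 2
  if (is.null(branchOffset)) branchOffset <- extent[2] / 4
  fork <- c(centre[1] * 0.8, centre[2], centre[3])
  prims <- list(
    list(type = "capsule", p1 = c(-2 * spacing[1], centre[2], centre[3]),
         p2 = fork, radius = parentRadius),
    list(type = "capsule", p1 = fork,
         p2 = c(extent[1] + 2 * spacing[1], centre[2] - branchOffset,
                centre[3]), radius = branchRadius),
    list(type = "capsule", p1 = fork,
         p2 = c(extent[1] + 2 * spacing[1], centre[2] + branchOffset,
                centre[3]), radius = branchRadius))
  spec <- phantomSpec(dims, prims, spacing = spacing, ...)
  epsGrid <- voxelizePartialVolume(spec)
  img <- renderIntensity(epsGrid, spec)
  sdf <- phantomSdf(prims)
  list(image = img, spec = spec, sdf = sdf,
       mesh = sdfMesh(sdf, dims, spacing), porosity = epsGrid)
}
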