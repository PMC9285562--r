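test_that("crop preserves values and world coordinates", {
  img <- VolumetricImage(array(as.numeric(1:512), c(8, 8, 8)),
                         spacing = c(0.5, 0.5, 0.4), origin = c(1, 2, 3))
  ## full-extent roi is the identity
  full <- cropVolume(img, c(0, 0, 0), c(8, 8, 8))
  expect_identical(full@data, img@data)
  expect_identical(full@origin, img@origin)
  ## values equal corresponding source voxels
  cr <- cropVolume(img, c(2, 3, 4), c(4, 5, 6))
  expect_identical(dim(cr@data), c(2L, 2L, 2L))
  expect_identical(cr@data[1, 1, 1], img@data[3, 4, 5])
  ## origin shift keeps world coordinates: voxel (0,0,0) of the crop must
  ## coincide with voxel (2,3,4) of the source
  expect_equal(worldCoordinates(cr, c(0, 0, 0)),
               worldCoordinates(img, c(2, 3, 4)))
  ## crop composition equals a single crop with intersected boxes
  c2 <- cropVolume(cropVolume(img, c(1, 1, 1), c(7, 7, 7)),
                   c(1, 2, 3), c(4, 5, 6))
  c1 <- cropVolume(img, c(2, 3, 4), c(5, 6, 7))
  expect_identical(c2@data, c1@data)
  expect_equal(c2@origin, c1@origin)
  expect_error(cropVolume(img, c(0, 0, 0), c(9, 8, 8)), "outside")
  expect_error(cropVolume(img, c(3, 0, 0), c(3, 8, 8)), "lower < upper")
})

test_that("isotropic resampling is exact for affine fields and bounded", {
  d <- c(9L, 9L, 7L)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  sp <- c(0.5, 0.5, 0.4)
  affine <- function(p) 2 * p[, 1] - 3 * p[, 2] + 0.5 * p[, 3] + 7
  w <- sweep(idx, 2, sp, "*")
  img <- VolumetricImage(array(affine(w), d), spacing = sp)
  out <- resampleIsotropic(img, 0.25)
  expect_equal(unname(out@spacing), rep(0.25, 3))
  oidx <- as.matrix(expand.grid(x = 0:(dim(out@data)[1] - 1),
                                y = 0:(dim(out@data)[2] - 1),
                                z = 0:(dim(out@data)[3] - 1)))
  expect_equal(as.numeric(out@data), affine(oidx * 0.25), tolerance = 1e-12)
  ## constant image stays constant at any target
  cimg <- VolumetricImage(array(5, d), spacing = sp)
  expect_true(all(resampleIsotropic(cimg, 0.17)@data == 5))
  ## trilinear convexity: never outside the input range
  set.seed(11)
  rimg <- VolumetricImage(array(rnorm(prod(d)), d), spacing = sp)
  rout <- resampleIsotropic(rimg, 0.21)
  expect_gte(min(rout@data), min(rimg@data))
  expect_lte(max(rout@data), max(rimg@data))
  ## extent in mm preserved within one voxel
  fine <- resampleIsotropic(img, 0.1)
  expect_lt(abs((dim(fine@data)[1] - 1) * 0.1 - (d[1] - 1) * sp[1]), 0.1)
  expect_error(resampleIsotropic(img, 100), "extent")
})

test_that("coarse thresholding keeps the closed interval", {
  vals <- c(40, 100, 250, 50, 200, 199.999, 50.0001, 249, 0)
  img <- VolumetricImage(array(vals, c(3, 3, 1)))
  m <- coarseThreshold(img, 50, 200)
  expect_identical(as.vector(m), vals >= 50 & vals <= 200)
  ## both endpoints retained (closed interval)
  expect_true(m[c(4)])   # exactly 50
  expect_true(m[c(5)])   # exactly 200
  ## all inside -> all true
  expect_true(all(coarseThreshold(img, -10, 300)))
  ## monotone: widening the range never removes voxels
  m2 <- coarseThreshold(img, 40, 250)
  expect_true(all(m2[m]))
})

test_that("contrast metrics match hand-computed moments and invariances", {
  d <- c(4, 4, 4)
  a <- array(0, d)
  ob <- array(FALSE, d); ob[1:2, , ] <- TRUE
  bg <- array(FALSE, d); bg[3:4, , ] <- TRUE
  a[ob] <- 100
  a[bg] <- rep(c(0, 2), 16)            # mean 1, population sd 1
  img <- VolumetricImage(a)
  cm <- contrastMetrics(img, ob, bg)
  expect_equal(cm@meanObject, 100)
  expect_equal(cm@meanBackground, 1)
  expect_equal(cm@sdBackground, 1)
  expect_equal(cm@cnr, 99)
  ## identical distributions give zero contrast
  a2 <- a; a2[ob] <- a[bg]
  cm0 <- contrastMetrics(VolumetricImage(a2), ob, bg)
  expect_equal(cm0@cnr, 0)
  ## intensity scaling leaves CNR unchanged
  cmS <- contrastMetrics(VolumetricImage(a * 3.7), ob, bg)
  expect_equal(cmS@cnr, cm@cnr)
  expect_equal(cmS@meanObject, 370)
  ## zero-variance background flagged
  a3 <- a; a3[bg] <- 5
  expect_warning(cmF <- contrastMetrics(VolumetricImage(a3), ob, bg),
                 "CNR undefined")
  expect_true(is.na(cmF@cnr))
  expect_error(contrastMetrics(img, ob, ob), "disjoint")
})
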