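test_that("intensity-to-porosity conversion is the linear mixing inverse", {
  img <- VolumetricImage(array(c(0, 100, 50, 120, -40), c(5, 1, 1)))
  pf <- porosityFromIntensity(img, If = 100, Is = 0)
  ## endpoints, midpoint, clipping
  expect_equal(as.vector(porosity(pf)), c(0, 1, 0.5, 1, 0))
  ## dark-fluid orientation (airway): roles swapped
  pfd <- porosityFromIntensity(img, If = 0, Is = 100)
  expect_equal(as.vector(porosity(pfd)), c(1, 0, 0.5, 0, 1))
  ## affine rescaling of (I, If, Is) leaves porosity unchanged
  img2 <- VolumetricImage(img@data * 3 + 11)
  pf2 <- porosityFromIntensity(img2, If = 100 * 3 + 11, Is = 11)
  expect_equal(porosity(pf2), porosity(pf))
  ## candidate mask zeroes excluded voxels
  m <- array(c(TRUE, TRUE, FALSE, TRUE, TRUE), c(5, 1, 1))
  pfm <- porosityFromIntensity(img, 100, 0, candidateMask = m)
  expect_equal(porosity(pfm)[3, 1, 1], 0)
  expect_true(solidMask(pfm)[3, 1, 1])
  expect_error(porosityFromIntensity(img, 5, 5), "must differ")
})

test_that("render/convert round-trip reproduces porosity exactly", {
  set.seed(3)
  eps <- array(runif(4 * 4 * 4), c(4, 4, 4))
  spec <- phantomSpec(4L, list(list(type = "sphere", center = c(0, 0, 0),
                                    radius = 1)), If = 180, Is = 20)
  img <- renderIntensity(eps, spec)   # noise and blur off by default
  back <- porosityFromIntensity(img, If = 180, Is = 20)
  expect_equal(porosity(back), eps, tolerance = 1e-12)
})

test_that("solidification uses the closed porosity cutoff", {
  eps <- array(c(0.1, 0.11, 0.0999, 1, 0.5, 0.2, 0.3, 1), c(2, 2, 2))
  pf <- new("PorosityField", epsilon = eps, solidMask = array(FALSE, c(2, 2, 2)),
            spacing = rep(1, 3), origin = rep(0, 3), epsMin = NA_real_)
  sf <- solidify(pf, 0.1)
  expect_true(sf@solidMask[1, 1, 1])    # exactly 0.1 is solid
  expect_false(sf@solidMask[2, 1, 1])   # 0.11 stays fluid
  expect_true(sf@solidMask[1, 2, 1])    # below cutoff
  ## all-fluid field has an empty solid mask
  pf1 <- uniformPorosityField(c(3, 3, 3), eps = 1)
  expect_equal(sum(solidify(pf1, 0.1)@solidMask), 0L)
  expect_error(solidify(pf, 1.2), "must lie")
})

test_that("shrunken-voxel resistance follows the calibrated law", {
  fluid <- FluidProps(1000, 1e-3)
  pf <- uniformPorosityField(c(2, 2, 2), eps = 0.5, spacingMm = 1)  # d = 1e-3 m
  rf <- shrunkenViscousResistance(pf, fluid)
  ## hand evaluation: 3 * 0.25 / (0.125 * 1e-6) * 1e-3 = 6e3
  expect_equal(viscousResistance(rf)[1, 1, 1], 6e3, tolerance = 1e-12)
  ## eps = 1 gives zero resistance
  rf1 <- shrunkenViscousResistance(uniformPorosityField(c(2, 2, 2), 1, 1),
                                   fluid)
  expect_equal(max(viscousResistance(rf1)), 0)
  ## strictly decreasing in porosity
  Pv <- vapply(c(0.2, 0.4, 0.6, 0.8), function(e)
    viscousResistance(shrunkenViscousResistance(
      uniformPorosityField(c(1, 1, 1), e, 1), fluid))[1, 1, 1], numeric(1))
  expect_true(all(diff(Pv) < 0))
  ## P_v scales as 1/d^2 at fixed porosity
  rfA <- shrunkenViscousResistance(uniformPorosityField(c(1, 1, 1), 0.5, 1),
                                   fluid)
  rfB <- shrunkenViscousResistance(uniformPorosityField(c(1, 1, 1), 0.5, 2),
                                   fluid)
  expect_equal(viscousResistance(rfA)[1] / viscousResistance(rfB)[1], 4,
               tolerance = 1e-12)
  ## inertial part defaults to zero
  expect_equal(max(abs(inertialResistance(rf))), 0)
})

test_that("packed-bed resistance matches the Blake-Kozeny constant", {
  fluid <- FluidProps(1000, 1e-3)
  ## 150 * 0.25 / 0.125 * 1e-3 / 1e-6 = 3e5
  expect_equal(packedBedViscousResistance(0.5, fluid, 1e-3), 3e5,
               tolerance = 1e-12)
  ## algebraic ratio between porosities
  r <- packedBedViscousResistance(0.4, fluid, 1e-3) /
    packedBedViscousResistance(0.5, fluid, 1e-3)
  expect_equal(r, (0.36 / 0.064) / (0.25 / 0.125), tolerance = 1e-12)
  ## vanishing in the open limit
  expect_lt(packedBedViscousResistance(1 - 1e-9, fluid, 1e-3), 1e-9)
  expect_error(packedBedViscousResistance(1, fluid, 1e-3), "0 < eps < 1")
})

test_that("Blake number evaluates the porous Reynolds analogue", {
  blood <- fluidPreset("blood")
  air <- fluidPreset("air")
  ## hand arithmetic with round numbers
  expect_equal(blakeNumber(1e-4, 0.5, 1e-3, FluidProps(1000, 1e-3)), 0.1,
               tolerance = 1e-12)
  expect_equal(blakeNumber(0, 0.5, 1e-3, blood), 0)
  ## fluid-property ratio at identical kinematics
  ratio <- blakeNumber(1e-4, 0.5, 1e-3, air) /
    blakeNumber(1e-4, 0.5, 1e-3, blood)
  expect_equal(ratio, (air@rho / air@mu) / (blood@rho / blood@mu),
               tolerance = 1e-12)
  expect_equal(blakeNumber(1e-4, 1, 1e-3, blood), Inf)
})
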