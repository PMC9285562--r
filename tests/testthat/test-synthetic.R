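test_that("partial-volume voxelization brackets the analytic fractions", {
  ## axis-aligned plane boundary: a capsule so large its surface is
  ## locally flat, bisecting the voxel column at a known height
  n <- 8L; sp <- 1
  big <- 1000
  prims <- list(list(type = "capsule", p1 = c(-10, 3.5 - big, 3.5),
                     p2 = c(20, 3.5 - big, 3.5), radius = big))
  spec <- phantomSpec(n, prims, spacing = sp)
  eps <- voxelizePartialVolume(spec, n = 4L)
  ## fluid occupies y-world < 3.5: voxels 1..4 inside, boundary voxel
  ## centre at y = 3 is fully inside, y = 4 fully outside, the plane cuts
  ## exactly between centres y = 3 and y = 4 at 3.5
  expect_equal(eps[4, 2, 4], 1)
  expect_equal(eps[4, 6, 4], 0)
  ## plane through a voxel centre: half full, to sub-sampling accuracy
  prims2 <- list(list(type = "capsule", p1 = c(-10, 3 - big, 3.5),
                      p2 = c(20, 3 - big, 3.5), radius = big))
  eps2 <- voxelizePartialVolume(phantomSpec(n, prims2, spacing = sp), n = 4L)
  expect_lt(abs(eps2[4, 4, 4] - 0.5), 1 / 4 + 1e-9)
  ## supersampling convergence on the half-cut voxel
  eps8 <- voxelizePartialVolume(phantomSpec(n, prims2, spacing = sp), n = 8L)
  expect_lte(abs(eps8[4, 4, 4] - 0.5), abs(eps2[4, 4, 4] - 0.5) + 1e-9)
})

test_that("intensity rendering is the exact affine map plus seeded noise", {
  prims <- list(list(type = "sphere", center = c(2, 2, 2), radius = 1.2))
  spec <- phantomSpec(16L, prims, spacing = 0.25, If = 200, Is = 0,
                      noiseSd = 0, seed = 5L)
  eps <- voxelizePartialVolume(spec)
  img <- renderIntensity(eps, spec)
  expect_equal(imageData(img), 0 + eps * 200, tolerance = 1e-12)
  ## with noise: fluid-core mean within 3 sd of If
  specN <- phantomSpec(16L, prims, spacing = 0.25, If = 200, Is = 0,
                       noiseSd = 8, seed = 5L)
  imgN <- renderIntensity(eps, specN)
  core <- eps == 1
  expect_lt(abs(mean(imageData(imgN)[core]) - 200),
            3 * 8 / sqrt(sum(core)))
  ## same seed twice: identical images
  imgN2 <- renderIntensity(eps, specN)
  expect_identical(imageData(imgN), imageData(imgN2))
  ## different seed differs
  specM <- phantomSpec(16L, prims, spacing = 0.25, If = 200, Is = 0,
                       noiseSd = 8, seed = 6L)
  expect_false(identical(imageData(renderIntensity(eps, specM)),
                         imageData(imgN)))
})

test_that("slice blur smears along z only and preserves constants", {
  prims <- list(list(type = "sphere", center = c(2, 2, 2), radius = 1))
  spec <- phantomSpec(c(12L, 12L, 12L), prims, spacing = 0.25,
                      sliceBlurSigmaZ = 0.5, If = 100, Is = 0)
  eps <- array(1, c(12, 12, 12))
  img <- renderIntensity(eps, spec)       # constant field: blur is identity
  expect_equal(range(imageData(img)), c(100, 100), tolerance = 1e-9)
  ## a z-step becomes a smooth ramp wider than one voxel
  eps2 <- array(0, c(12, 12, 12)); eps2[, , 1:6] <- 1
  img2 <- renderIntensity(eps2, spec)
  profile <- imageData(img2)[6, 6, ]
  expect_gt(sum(profile > 5 & profile < 95), 2)
  ## no smearing in-plane
  expect_equal(imageData(img2)[1, 1, ], profile, tolerance = 1e-9)
})

test_that("aneurysm phantom ground truth is consistent and contrasted", {
  ph <- aneurysmPhantom(dims = 48L, tubeRadius = 0.7, sacRadius = 1.1,
                        spacing = 0.12, noiseSd = 10, seed = 2L)
  expect_true(isWatertight(ph$mesh))
  ## reference mesh volume vs an independent fine quadrature of the SDF
  d <- ph$spec$dims; sp <- ph$spec$spacing
  ## integrate over the sampled box [0, extent] that the mesh is clipped to
  f <- 3L
  extent <- (d - 1L) * sp
  ns <- d * f
  pts <- as.matrix(expand.grid(
    x = (seq_len(ns[1]) - 0.5) / ns[1] * extent[1],
    y = (seq_len(ns[2]) - 0.5) / ns[2] * extent[2],
    z = (seq_len(ns[3]) - 0.5) / ns[3] * extent[3]))
  vQuad <- sum(ph$sdf(pts) < 0) * prod(extent / ns)
  expect_lt(abs(meshVolume(ph$mesh) - vQuad) / vQuad, 0.01)
  ## CNR is controllable: (If - Is) / noise sd by construction
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  sd0 <- ph$sdf(worldCoordinates(ph$image, idx))
  ob <- array(sd0 < -2 * sp[1], d)
  bg <- array(sd0 > 2 * sp[1], d)
  cm <- contrastMetrics(ph$image, ob, bg)
  expect_equal(cm@cnr, (200 - 0) / 10, tolerance = 0.15)
  ## sac radius zero degenerates to a plain tube
  tube <- aneurysmPhantom(dims = 32L, tubeRadius = 0.7, sacRadius = 0,
                          spacing = 0.12)
  expect_equal(length(tube$spec$primitives), 1L)
  expect_error(aneurysmPhantom(dims = 32L, tubeRadius = 0.7, sacRadius = 0.5,
                               neckOffset = 5, spacing = 0.12),
               "disconnected")
})

test_that("parallel channels stay separated through the pipeline field", {
  ph <- channelPhantom(dims = c(32L, 24L, 16L), channelRadius = 0.35,
                       spacing = 0.1, If = 200, Is = 0)
  ## porosity grid has two disjoint fluid tubes
  expect_equal(range(ph$porosity), c(0, 1))
  mid <- ph$porosity[16, , 8]
  runs <- rle(mid > 0.5)
  expect_equal(sum(runs$values), 2L)   # two fluid runs across y
  ## ground-truth surface has two components
  expect_equal(ph$mesh@ncomp, 2L)
})

test_that("symmetric bifurcation splits the outlet flux evenly", {
  ph <- bifurcationPhantom(dims = c(32L, 32L, 16L), parentRadius = 0.5,
                           branchRadius = 0.45, spacing = 0.12)
  pf <- solidify(new("PorosityField", epsilon = ph$porosity,
                     solidMask = array(FALSE, dim(ph$porosity)),
                     spacing = ph$image@spacing, origin = ph$image@origin,
                     epsMin = NA_real_), 0.1)
  fluid <- fluidPreset("blood")
  rf <- shrunkenViscousResistance(pf, fluid)
  dom <- buildFlowDomain(pf, rf, boundarySpec("x-"), boundarySpec("x+"))
  sol <- solveCreepingFlow(dom, fluid, solverConfig(tol = 1e-9))
  mb <- massBalanceReport(sol, dom)
  expect_lt(mb$relativeImbalance, 1e-6)
  ## flux through the upper and lower halves of the outlet is symmetric
  uOut <- sol@u[dim(sol@u)[1], , ]
  ny <- dim(uOut)[1]
  qLow <- sum(uOut[1:(ny / 2), ]); qHigh <- sum(uOut[(ny / 2 + 1):ny, ])
  expect_equal(qLow, qHigh, tolerance = 1e-4)
})
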