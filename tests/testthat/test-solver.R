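makeOpenDuct <- function(dims, spacingMm = 0.1) {
  pf <- uniformPorosityField(dims, eps = 1, spacingMm = spacingMm)
  rf <- zeroResistanceField(dims, spacingMm)
  list(pf = pf, rf = rf)
}

test_that("open rectangular duct matches the Poiseuille series solution", {
  nc <- 16L; nx <- 24L
  spMm <- 0.1; h <- spMm * 1e-3
  a <- nc * h; b <- nc * h
  fluid <- fluidPreset("blood")
  ## choose the pressure gradient whose mean velocity is 1e-4 m/s
  ys <- (seq_len(120) - 0.5) / 120 * a
  U1 <- outer(ys, ys, function(y, z)
    ductSeriesProfile(y, z, a, b, 1, fluid@mu))
  Gs <- 1e-4 / mean(U1)
  duct <- makeOpenDuct(c(nx, nc, nc), spMm)
  prof <- function(t1, t2)
    ductSeriesProfile(t1 * 1e-3 + h / 2, t2 * 1e-3 + h / 2, a, b, Gs,
                      fluid@mu)
  dom <- buildFlowDomain(duct$pf, duct$rf,
                         boundarySpec("x-", profile = prof),
                         boundarySpec("x+"))
  sol <- solveCreepingFlow(dom, fluid, solverConfig(tol = 1e-10))
  ya <- ((seq_len(nc)) - 0.5) * h
  ua <- outer(ya, ya, function(y, z)
    ductSeriesProfile(y, z, a, b, Gs, fluid@mu))
  err <- max(abs(sol@u[nx / 2, , ] - ua)) / max(ua)
  expect_lt(err, 0.01)
  ## mass balance of the converged case
  mb <- massBalanceReport(sol, dom)
  expect_lt(mb$relativeImbalance, 1e-6)
})

test_that("uniform porous slab reproduces the Darcy limit", {
  dims <- c(24L, 6L, 6L)
  fluid <- fluidPreset("blood")
  pf <- uniformPorosityField(dims, eps = 0.5)
  rf <- shrunkenViscousResistance(pf, fluid)
  dom <- buildFlowDomain(pf, rf, boundarySpec("x-"), boundarySpec("x+"),
                         symmetrySides = c("y-", "y+", "z-", "z+"))
  sol <- solveCreepingFlow(dom, fluid,
                           solverConfig(inletSpeed = 1e-4, tol = 1e-10))
  h <- 1e-4
  Pv <- viscousResistance(rf)[1, 1, 1]
  dpdx <- (sol@pressure[6, 3, 3] - sol@pressure[18, 3, 3]) / (12 * h)
  expect_lt(abs(dpdx - Pv * 1e-4) / (Pv * 1e-4), 0.005)
  ## plug flow: interior velocity uniform at the superficial inlet speed
  expect_equal(range(sol@speed[6:18, , ]), c(1e-4, 1e-4), tolerance = 1e-9)
})

test_that("the solver is linear in the inlet speed and deterministic", {
  dims <- c(16L, 8L, 8L)
  pf <- uniformPorosityField(dims, eps = 1)
  pf@epsilon[8:10, 3:6, 3:6] <- 0.4   # a porous obstacle
  fluid <- fluidPreset("blood")
  rf <- shrunkenViscousResistance(pf, fluid)
  dom <- buildFlowDomain(pf, rf, boundarySpec("x-"), boundarySpec("x+"))
  s1 <- solveCreepingFlow(dom, fluid, solverConfig(inletSpeed = 1e-4,
                                                   tol = 1e-11))
  s2 <- solveCreepingFlow(dom, fluid, solverConfig(inletSpeed = 2e-4,
                                                   tol = 1e-11))
  expect_equal(s2@speed, 2 * s1@speed, tolerance = 1e-7)
  expect_equal(s2@pressure, 2 * s1@pressure, tolerance = 1e-7)
  ## re-solve is bitwise identical (no random initialisation)
  s1b <- solveCreepingFlow(dom, fluid, solverConfig(inletSpeed = 1e-4,
                                                    tol = 1e-11))
  expect_identical(s1@speed, s1b@speed)
})

test_that("zero inflow yields the zero solution", {
  dims <- c(12L, 6L, 6L)
  duct <- makeOpenDuct(dims)
  dom <- buildFlowDomain(duct$pf, duct$rf, boundarySpec("x-"),
                         boundarySpec("x+"))
  sol <- solveCreepingFlow(dom, fluidPreset("blood"),
                           solverConfig(inletSpeed = 0))
  expect_equal(max(sol@speed), 0)
  expect_equal(max(abs(sol@pressure), na.rm = TRUE), 0)
})

test_that("multiple outlets conserve mass and support branching", {
  dims <- c(16L, 16L, 8L)
  duct <- makeOpenDuct(dims)
  dom <- buildFlowDomain(duct$pf, duct$rf, boundarySpec("x-"),
                         list(boundarySpec("x+"), boundarySpec("y+")))
  sol <- solveCreepingFlow(dom, fluidPreset("blood"),
                           solverConfig(inletSpeed = 1e-4, tol = 1e-10))
  mb <- massBalanceReport(sol, dom)
  ## the two outlet fluxes sum to the inlet flux
  expect_lt(mb$relativeImbalance, 1e-6)
  expect_gt(mb$outletFlux, 0)
})

test_that("added resistance increases the inlet-to-outlet pressure drop", {
  dims <- c(16L, 6L, 6L)
  fluid <- fluidPreset("blood")
  pfA <- uniformPorosityField(dims, eps = 1)
  pfB <- uniformPorosityField(dims, eps = 1)
  pfB@epsilon[8:9, , ] <- 0.5
  cfg <- solverConfig(inletSpeed = 1e-4, tol = 1e-10)
  drop <- function(pf) {
    rf <- shrunkenViscousResistance(pf, fluid)
    dom <- buildFlowDomain(pf, rf, boundarySpec("x-"), boundarySpec("x+"))
    sol <- solveCreepingFlow(dom, fluid, cfg)
    mean(sol@pressure[1, , ])
  }
  expect_gt(drop(pfB), drop(pfA) * 1.5)
})

test_that("mirror-symmetric domains give mirror-symmetric solutions", {
  dims <- c(16L, 9L, 9L)
  pf <- uniformPorosityField(dims, eps = 1)
  pf@epsilon[6:8, 4:6, 4:6] <- 0.3     # centred obstacle
  fluid <- fluidPreset("blood")
  rf <- shrunkenViscousResistance(pf, fluid)
  dom <- buildFlowDomain(pf, rf, boundarySpec("x-"), boundarySpec("x+"))
  sol <- solveCreepingFlow(dom, fluid, solverConfig(tol = 1e-11))
  flipped <- sol@speed[, rev(seq_len(dims[2])), ]
  expect_equal(sol@speed, flipped, tolerance = 1e-6)
})

test_that("domain construction validates boundary specs and prunes cells", {
  dims <- c(8L, 8L, 8L)
  pf <- uniformPorosityField(dims, eps = 1)
  ## solid face blocks the chosen inlet side entirely
  pf@solidMask[1, , ] <- TRUE
  pf@epsilon[1, , ] <- 0
  rf <- zeroResistanceField(dims)
  expect_error(buildFlowDomain(pf, rf, boundarySpec("x-"),
                               boundarySpec("x+")),
               "selects no fluid-adjacent faces")
  ## no path from inlet to outlet
  pf2 <- uniformPorosityField(dims, eps = 1)
  pf2@solidMask[4, , ] <- TRUE
  expect_error(buildFlowDomain(pf2, rf, boundarySpec("x-"),
                               boundarySpec("x+")),
               "no fluid path")
  ## a fluid cell walled in on all six sides is reassigned to solid
  pf3 <- uniformPorosityField(dims, eps = 1)
  for (nb in list(c(3, 4, 4), c(5, 4, 4), c(4, 3, 4), c(4, 5, 4),
                  c(4, 4, 3), c(4, 4, 5)))
    pf3@solidMask[nb[1], nb[2], nb[3]] <- TRUE
  expect_message(dom3 <- buildFlowDomain(pf3, rf, boundarySpec("x-"),
                                         boundarySpec("x+")),
                 "isolated")
  expect_false(dom3@fluidMask[4, 4, 4])
})

test_that("cell-centred speed averages opposing faces", {
  ## uniform unidirectional flow: speed equals the constant everywhere
  dims <- c(6L, 5L, 4L)
  mask <- array(TRUE, dims)
  vel <- list(array(3e-4, dims + c(1, 0, 0)),
              array(0, dims + c(0, 1, 0)),
              array(0, dims + c(0, 0, 1)))
  expect_equal(max(abs(poroseg:::cellSpeed(vel, mask) - 3e-4)), 0)
  ## rigid-rotation-like field sampled on faces: magnitude recovered at
  ## centres within the averaging error
  h <- 1
  ufun <- function(y) -y; vfun <- function(x) x
  u <- array(0, dims + c(1, 0, 0)); v <- array(0, dims + c(0, 1, 0))
  for (j in seq_len(dims[2])) u[, j, ] <- ufun((j - 0.5) * h)
  for (i in seq_len(dims[1])) v[i, , ] <- vfun((i - 0.5) * h)
  sp <- poroseg:::cellSpeed(list(u, v, array(0, dims + c(0, 0, 1))), mask)
  cx <- (seq_len(dims[1]) - 0.5) * h; cy <- (seq_len(dims[2]) - 0.5) * h
  expect_equal(sp[, , 1], outer(cx, cy, function(x, y) sqrt(x^2 + y^2)),
               tolerance = 1e-12)
  ## all-zero solution gives all-zero speed
  zero <- list(array(0, dims + c(1, 0, 0)), array(0, dims + c(0, 1, 0)),
               array(0, dims + c(0, 0, 1)))
  expect_equal(max(poroseg:::cellSpeed(zero, mask)), 0)
})
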