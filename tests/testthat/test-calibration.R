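test_that("analytic channel gradient is the plane-Poiseuille closed form", {
  fluid <- FluidProps(1000, 1e-3)
  ## open channel: 3 mu v / d^2
  c1 <- channelCase(1e-3, 1, 1, fluid)
  expect_equal(channelPressureDropAnalytic(c1), 3e3, tolerance = 1e-12)
  ## halving porosity quadruples the gradient
  c2 <- channelCase(1e-3, 0.5, 1, fluid)
  expect_equal(channelPressureDropAnalytic(c2) /
                 channelPressureDropAnalytic(c1), 4, tolerance = 1e-12)
  ## linear in velocity
  c3 <- channelCase(1e-3, 0.5, 2, fluid)
  expect_equal(channelPressureDropAnalytic(c3) /
                 channelPressureDropAnalytic(c2), 2, tolerance = 1e-12)
})

test_that("numeric channel solves converge to the analytic oracle", {
  case <- channelCase(5e-4, 0.6, 1e-3)
  an <- channelPressureDropAnalytic(case)
  errs <- vapply(c(16L, 32L, 64L), function(res)
    abs(channelPressureDropNumeric(case, res) - an) / an, numeric(1))
  ## within 0.5% at 64 cells and monotone under refinement
  expect_lt(errs[3], 0.005)
  expect_true(all(diff(errs) < 0))
  ## fully open voxel recovers the open-channel gradient
  open <- channelCase(5e-4, 1, 1e-3)
  expect_lt(abs(channelPressureDropNumeric(open, 32L) -
                  channelPressureDropAnalytic(open)) /
              channelPressureDropAnalytic(open), 0.005)
})

test_that("shrunken-voxel friction points collapse onto f_b Re_b = 3", {
  fluid <- fluidPreset("blood")
  grid <- expand.grid(d = c(2.5e-4, 1e-3), eps = c(0.3, 0.7, 1),
                      v = c(1e-3, 0.5))
  for (i in seq_len(nrow(grid))) {
    case <- channelCase(grid$d[i], grid$eps[i], grid$v[i], fluid)
    fp <- frictionPointShrunken(case, channelPressureDropAnalytic(case))
    expect_equal(fp$fb * fp$Reb, 3, tolerance = 1e-12)
  }
  ## equal Re_b across different porosity gives equal f_b (collapse):
  ## match Re_b by adjusting velocity
  cA <- channelCase(1e-3, 0.4, 1e-2, fluid)
  vB <- 1e-2 * 0.4 / 0.8
  cB <- channelCase(1e-3, 0.8, vB, fluid)
  fA <- frictionPointShrunken(cA, channelPressureDropAnalytic(cA))
  fB <- frictionPointShrunken(cB, channelPressureDropAnalytic(cB))
  expect_equal(fA$Reb, fB$Reb, tolerance = 1e-12)
  expect_equal(fA$fb, fB$fb, tolerance = 1e-12)
  ## hyperbola: doubling Re_b halves f_b in the creeping regime
  cC <- channelCase(1e-3, 0.4, 2e-2, fluid)
  fC <- frictionPointShrunken(cC, channelPressureDropAnalytic(cC))
  expect_equal(fC$fb, fA$fb / 2, tolerance = 1e-12)
})

test_that("packed-bed non-dimensionalisation does not collapse", {
  fluid <- fluidPreset("blood")
  ## same data, different definitions
  case <- channelCase(1e-3, 0.5, 1e-2, fluid)
  dpdl <- channelPressureDropAnalytic(case)
  sh <- frictionPointShrunken(case, dpdl)
  pk <- frictionPointPacked(case, dpdl)
  expect_false(isTRUE(all.equal(sh$fb, pk$fb)))
  expect_false(isTRUE(all.equal(sh$Reb, pk$Reb)))
  ## cubic voxel: Re_b reduces to rho v d / mu
  expect_equal(pk$Reb, fluid@rho * 1e-2 * 1e-3 / fluid@mu, tolerance = 1e-12)
  ## fixed Re_b, varying porosity: distinct f_b values
  fbs <- vapply(c(0.3, 0.5, 0.7, 0.9), function(e) {
    cs <- channelCase(1e-3, e, 1e-2, fluid)
    frictionPointPacked(cs, channelPressureDropAnalytic(cs))$fb
  }, numeric(1))
  expect_gt(diff(range(fbs)) / mean(fbs), 0.5)
  expect_error(frictionPointPacked(channelCase(1e-3, 1, 1e-2, fluid), 1),
               "degenerate")
})

test_that("least-squares fit recovers exact and noisy constants", {
  ## exact hyperbola A = 3, B = 0
  Reb <- 10^seq(-2, 3, length.out = 12)
  pts <- data.frame(fb = 3 / Reb, Reb = Reb)
  fit <- fitErgunConstants(pts)
  expect_equal(fit@A, 3, tolerance = 1e-12)
  expect_equal(fit@B, 0, tolerance = 1e-10)
  expect_lt(fit@rmsResidual, 1e-10)
  ## known non-zero intercept is recovered too
  pts2 <- data.frame(fb = 3 / Reb + 1.75, Reb = Reb)
  fit2 <- fitErgunConstants(pts2)
  expect_equal(fit2@A, 3, tolerance = 1e-12)
  expect_equal(fit2@B, 1.75, tolerance = 1e-10)
  ## 1% multiplicative noise leaves A within 3% (seeded Monte-Carlo)
  set.seed(42)
  pts3 <- data.frame(fb = 3 / Reb * (1 + rnorm(length(Reb), sd = 0.01)),
                     Reb = Reb)
  expect_lt(abs(fitErgunConstants(pts3)@A - 3) / 3, 0.03)
  expect_error(fitErgunConstants(data.frame(fb = c(1, 2), Reb = c(5, 5))),
               "distinct")
})

test_that("collapse diagnostic separates the two voxel models", {
  fluid <- fluidPreset("blood")
  grid <- expand.grid(eps = c(0.3, 0.5, 0.7, 0.9),
                      v = 10^seq(-3, 0, length.out = 4))
  pts <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    case <- channelCase(1e-3, grid$eps[i], grid$v[i], fluid)
    dpdl <- channelPressureDropAnalytic(case)
    cbind(frictionPointShrunken(case, dpdl)[, c("fb", "Reb", "eps")],
          fbP = frictionPointPacked(case, dpdl)$fb,
          RebP = frictionPointPacked(case, dpdl)$Reb)
  }))
  shCv <- collapseDiagnostic(pts[, c("fb", "Reb", "eps")])
  expect_lt(shCv$cv, 1e-6)
  expect_true(all(abs(shCv$groupA - 3) < 1e-9))
  pk <- data.frame(fb = pts$fbP, Reb = pts$RebP, eps = pts$eps)
  expect_gt(collapseDiagnostic(pk)$cv, 0.1)
  one <- pts[pts$eps == 0.3, c("fb", "Reb", "eps")]
  expect_error(collapseDiagnostic(one), "at least 3")
})
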