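## Calibration of the shrunken-voxel constants A and B.  A partially
## occupied voxel of height d and porosity eps is modelled as a 2-D channel
## whose fluid strip has height eps*d (no-slip bottom wall where the solid
## slab sits, shear-free symmetry top).  Creeping-flow pressure drops are
## non-dimensionalised into friction factor / bed Reynolds number pairs and
## f_b = A / Re_b + B is fitted by unweighted least squares.

#' A single-voxel channel case
#'
#' @param d voxel height, metres.
#' @param eps porosity in (0, 1]; the fluid strip has height `eps * d`.
#' @param vIn mean inlet (physical) velocity, m s^-1.
#' @param fluid a [FluidProps-class].
#' @param da voxel depth, metres (used only by the packed-bed
#'   non-dimensionalisation); defaults to `d` (cubic voxel).
#' @return A channel case (list).
#' @export
channelCase <- function(d, eps, vIn, fluid = fluidPreset("blood"), da = d) {
  assertThat(eps > 0 && eps <= 1, "eps must lie in (0, 1]")
  assertThat(d > 0 && vIn > 0 && da > 0, "d, vIn and da must be positive")
  list(d = d, eps = eps, vIn = vIn, fluid = fluid, da = da)
}

#' Analytic channel pressure gradient (plane-Poiseuille closed form)
#'
#' For a channel of height `eps * d` with a no-slip bottom and shear-free
#' top carrying mean velocity v, the streamwise pressure gradient is
#' \deqn{\Delta p / L = 3 \mu v / (\varepsilon d)^2.}
#' Serves as the exact oracle for the numeric solver.
#'
#' @param case a [channelCase()].
#' @return Pressure gradient, Pa m^-1.
#' @export
channelPressureDropAnalytic <- function(case) {
  3 * case$fluid@mu * case$vIn / (case$eps * case$d)^2
}

#' Numeric channel pressure gradient (2-D creeping-flow solve)
#'
#' Solves steady creeping flow in the fluid strip of the voxel channel
#' (the solid slab is excluded from the mesh): no-slip bottom wall,
#' symmetry top, prescribed fully developed half-parabolic inflow, zero
#' outlet pressure.  Returns the streamwise pressure gradient measured
#' between the quarter and three-quarter sections.
#'
#' @param case a [channelCase()].
#' @param resolution cells across the fluid-strip height (>= 8).
#' @param aspect channel length in units of the strip height.
#' @return Pressure gradient, Pa m^-1.
#' @export
channelPressureDropNumeric <- function(case, resolution = 64L, aspect = 2) {
  assertThat(resolution >= 8L, "need at least 8 cells across the fluid strip")
  hF <- case$eps * case$d              # fluid strip height, m
  dy <- hF / resolution                # cell size, m
  ny <- as.integer(resolution)
  nx <- as.integer(round(aspect * resolution))
  spacingMm <- dy * 1e3
  dims <- c(nx, ny, 1L)
  eps <- array(1, dims)
  pf <- new("PorosityField", epsilon = eps,
            solidMask = array(FALSE, dims),
            spacing = rep(spacingMm, 3L), origin = c(0, 0, 0), epsMin = 0.1)
  rf <- new("ResistanceField", Pv = array(0, dims), Pi = array(0, dims),
            d = dy, spacing = rep(spacingMm, 3L), origin = c(0, 0, 0))
  v <- case$vIn
  profile <- function(t1, t2) {
    ## wall surface sits half a cell below the first cell centre
    yw <- t1 * 1e-3 + dy / 2
    eta <- yw / hF
    1.5 * v * (2 * eta - eta^2)
  }
  dom <- buildFlowDomain(pf, rf,
                         inlets = boundarySpec("x-", profile = profile),
                         outlets = boundarySpec("x+"),
                         symmetrySides = c("y+", "z-", "z+"))
  cfg <- solverConfig(inletSpeed = v, tol = 1e-10, method = "schur")
  sol <- solveCreepingFlow(dom, case$fluid, cfg)
  i1 <- max(1L, round(nx * 0.25)); i2 <- min(nx, round(nx * 0.75))
  p1 <- mean(sol@pressure[i1, , 1]); p2 <- mean(sol@pressure[i2, , 1])
  (p1 - p2) / ((i2 - i1) * dy)
}

#' Shrunken-voxel friction point
#'
#' Non-dimensionalises a channel pressure drop with the shrunken-voxel
#' hydraulic radius (eps * d):
#' f_b = (dp/L) eps d / (rho v^2), Re_b = eps rho v d / mu, so that the
#' model relation reads f_b = A / Re_b + B.
#'
#' @param case a [channelCase()].
#' @param dpdl pressure gradient, Pa m^-1 (> 0).
#' @return One-row data.frame: fb, Reb, eps, d, vIn, model.
#' @export
frictionPointShrunken <- function(case, dpdl) {
  assertThat(dpdl > 0, "pressure gradient must be positive")
  rho <- case$fluid@rho; mu <- case$fluid@mu
  data.frame(fb = dpdl * case$eps * case$d / (rho * case$vIn^2),
             Reb = case$eps * rho * case$vIn * case$d / mu,
             eps = case$eps, d = case$d, vIn = case$vIn,
             model = "shrunken", stringsAsFactors = FALSE)
}

#' Packed-bed-voxel friction point
#'
#' Non-dimensionalises the same pressure drop with the packed-bed voxel
#' model (spherical particles matching the solid volume):
#' f_b = (dp/L) eps^2 (d^2 da)^{1/3} / (rho v^2 (1-eps)^{2/3}),
#' Re_b = rho v (d^2 da)^{1/3} / mu.  Distinct porosities fall on distinct
#' lines (non-collapse), which is why the shrunken model is preferred.
#'
#' @inheritParams frictionPointShrunken
#' @return One-row data.frame: fb, Reb, eps, d, vIn, model.
#' @export
frictionPointPacked <- function(case, dpdl) {
  assertThat(dpdl > 0, "pressure gradient must be positive")
  assertThat(case$eps < 1, "packed-bed form is degenerate at eps = 1")
  rho <- case$fluid@rho; mu <- case$fluid@mu
  dEff <- (case$d^2 * case$da)^(1 / 3)
  data.frame(fb = dpdl * case$eps^2 * dEff /
               (rho * case$vIn^2 * (1 - case$eps)^(2 / 3)),
             Reb = rho * case$vIn * dEff / mu,
             eps = case$eps, d = case$d, vIn = case$vIn,
             model = "packed", stringsAsFactors = FALSE)
}

#' Least-squares fit of the friction-factor relation
#'
#' Unweighted linear least squares of f_b = A / Re_b + B in the
#' (1/Re_b, 1) design.
#'
#' @param points data.frame with columns `fb` and `Reb` (>= 2 distinct
#'   Re_b values).
#' @return A [FitResult-class].
#' @export
fitErgunConstants <- function(points) {
  assertThat(nrow(points) >= 2L && length(unique(points$Reb)) >= 2L,
             "need at least 2 distinct Re_b values")
  fit <- lm(fb ~ I(1 / Reb), data = points)
  cf <- coef(fit)
  new("FitResult", A = unname(cf[2]), B = unname(cf[1]),
      rmsResidual = sqrt(mean(fit$residuals^2)), n = nrow(points))
}

#' Collapse diagnostic across porosity groups
#'
#' Fits the viscous constant A separately per porosity group and returns
#' the coefficient of variation of the group-wise constants: near zero for
#' the shrunken-voxel non-dimensionalisation (all porosities collapse on
#' one line), large for the packed-bed one.
#'
#' @param points data.frame with columns `fb`, `Reb`, `eps` covering at
#'   least 3 porosity groups.
#' @return List: `cv`, `groupA` (named per-porosity constants).
#' @export
collapseDiagnostic <- function(points) {
  groups <- split(points, points$eps)
  assertThat(length(groups) >= 3L, "need at least 3 porosity groups")
  groupA <- vapply(groups, function(g) {
    if (length(unique(g$Reb)) >= 2L) unname(coef(lm(fb ~ I(1 / Reb),
                                                    data = g))[2])
    else g$fb[1] * g$Reb[1]          # single point: A = fb * Reb (B = 0)
  }, numeric(1))
  list(cv = sd(groupA) / mean(groupA), groupA = groupA)
}

#' Default calibration campaign (reduced single-voxel channel grid)
#'
#' Voxel heights d in \{0.25, 1.0\} mm, porosities \{0.3, 0.5, 0.7, 0.9\},
#' four inlet velocities log-spaced in [5e-4, 4] m/s: a reduced subset of
#' the full campaign (4 heights x 10 porosities x 15 velocities), justified
#' because the creeping-flow relation is exact rather than statistical.
#'
#' @param d voxel heights, metres.
#' @param eps porosities.
#' @param v inlet velocities, m s^-1.
#' @param fluid a [FluidProps-class].
#' @return data.frame of cases.
#' @export
calibrationCampaign <- function(d = c(0.25e-3, 1.0e-3),
                                eps = c(0.3, 0.5, 0.7, 0.9),
                                v = 10^seq(log10(5e-4), log10(4),
                                           length.out = 4),
                                fluid = fluidPreset("blood")) {
  grid <- expand.grid(d = d, eps = eps, vIn = v, KEEP.OUT.ATTRS = FALSE)
  attr(grid, "fluid") <- fluid
  grid
}

#' Run the calibration campaign and fit the shrunken-voxel constants
#'
#' For each case, computes the channel pressure gradient (2-D numeric
#' creeping-flow solve, or the plane-Poiseuille closed form when
#' `numeric = FALSE`), both non-dimensionalisations, and the least-squares
#' fit of f_b = A / Re_b + B on the shrunken-voxel points.
#'
#' @param campaign data.frame from [calibrationCampaign()].
#' @param numeric use the 2-D numeric solver (TRUE) or the analytic closed
#'   form (FALSE).
#' @param resolution cells across the fluid strip for the numeric solver.
#' @return List: `fit` ([FitResult-class]), `table` (one row per case with
#'   dpdl and both friction-point forms), `collapse` (per-model collapse
#'   diagnostics).
#' @export
runCalibration <- function(campaign = calibrationCampaign(), numeric = TRUE,
                           resolution = 64L) {
  fluid <- attr(campaign, "fluid")
  if (is.null(fluid)) fluid <- fluidPreset("blood")
  rows <- lapply(seq_len(nrow(campaign)), function(i) {
    case <- channelCase(campaign$d[i], campaign$eps[i], campaign$vIn[i],
                        fluid)
    dpdl <- if (numeric) channelPressureDropNumeric(case, resolution)
            else channelPressureDropAnalytic(case)
    sh <- frictionPointShrunken(case, dpdl)
    pk <- frictionPointPacked(case, dpdl)
    data.frame(d = case$d, eps = case$eps, vIn = case$vIn, dpdl = dpdl,
               fbShrunken = sh$fb, RebShrunken = sh$Reb,
               fbPacked = pk$fb, RebPacked = pk$Reb)
  })
  tb <- do.call(rbind, rows)
  shPoints <- data.frame(fb = tb$fbShrunken, Reb = tb$RebShrunken,
                         eps = tb$eps)
  pkPoints <- data.frame(fb = tb$fbPacked, Reb = tb$RebPacked, eps = tb$eps)
  list(fit = fitErgunConstants(shPoints), table = tb,
       collapse = list(shrunken = collapseDiagnostic(shPoints),
                       packed = collapseDiagnostic(pkPoints)))
}
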