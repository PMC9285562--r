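## Steady incompressible creeping flow with a per-voxel porous viscous sink
## (Stokes-Brinkman):
##   div(v_s) = 0,   0 = -grad p + mu lap(v_s) - P_v v_s
## on a marker-and-cell staggered grid: face-normal superficial velocities,
## cell-centred pressures, 7-point Laplacians, face resistance as the mean of
## adjacent cell P_v.  Inlet: prescribed normal velocity; outlet: zero ghost
## pressure with zero normal velocity gradient; walls: no-slip (half-cell
## mirror ghost); symmetry sides: shear-free.  The saddle-point system is
## solved by a sparse direct factorisation for small problems and by
## conjugate gradients on the pressure Schur complement (velocity blocks
## Cholesky-factored once) above a size threshold.

SIDES <- c("x-", "x+", "y-", "y+", "z-", "z+")

sideAxis <- function(side) match(substr(side, 1, 1), c("x", "y", "z"))
sideHigh <- function(side) substr(side, 2, 2) == "+"

#' Boundary face specification
#'
#' Selects exterior faces of the flow domain on one bounding-box side, with
#' an optional in-plane mask, for use as an inlet or outlet.
#'
#' @param side one of `"x-"`, `"x+"`, `"y-"`, `"y+"`, `"z-"`, `"z+"`.
#' @param mask optional logical matrix over the two tangential axes (in
#'   axis order, e.g. (ny, nz) for an x side); `NULL` selects the whole side.
#' @param speed optional inlet speed override, m s^-1 (positive = into the
#'   domain); defaults to the solver config inlet speed.
#' @param profile optional function `f(t1, t2)` of the two tangential world
#'   coordinates (mm, vectorised) returning the inlet speed per face,
#'   m s^-1; overrides `speed`.
#' @return A boundary spec (list) for [buildFlowDomain()].
#' @export
boundarySpec <- function(side, mask = NULL, speed = NULL, profile = NULL) {
  assertThat(side %in% SIDES, "side must be one of x-,x+,y-,y+,z-,z+")
  list(side = side, mask = mask, speed = speed, profile = profile)
}

#' Solver configuration
#'
#' @param inletSpeed default uniform inlet velocity magnitude, m s^-1.
#' @param tol relative residual tolerance of the linear solve.
#' @param maxIter iteration cap for the Schur-complement conjugate gradient.
#' @param method `"auto"` (direct below `directMaxUnknowns` unknowns, Schur
#'   CG above), `"direct"`, or `"schur"`.
#' @param directMaxUnknowns size threshold for the direct factorisation.
#' @return A config list for [solveCreepingFlow()].
#' @export
solverConfig <- function(inletSpeed = 1e-4, tol = 1e-8, maxIter = 20000L,
                         method = c("auto", "direct", "schur"),
                         directMaxUnknowns = 30000L) {
  assertThat(tol > 0, "tolerance must be positive")
  list(inletSpeed = inletSpeed, tol = tol, maxIter = as.integer(maxIter),
       method = match.arg(method),
       directMaxUnknowns = as.integer(directMaxUnknowns))
}

## shift a logical/numeric 3-D array by one cell along axis, filling with
## `fill`; shift = +1 brings a[i-1] to position i
shift3 <- function(a, axis, by, fill) {
  d <- dim(a)
  out <- array(fill, d)
  if (d[axis] < 2L) return(out)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1L) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1L) }
  else          { dst[[axis]] <- 1:(d[axis] - 1L); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Build a flow domain from solidified porosity and resistance fields
#'
#' Exterior faces of the fluid region default to no-slip walls; inlet and
#' outlet specs label faces on bounding-box sides.  Isolated fluid cells
#' (no fluid neighbour) and fluid components not connected to both an inlet
#' and an outlet are reassigned to solid, with a message.
#'
#' @param pf a solidified [PorosityField-class].
#' @param rf the matching [ResistanceField-class] from
#'   [shrunkenViscousResistance()].
#' @param inlets,outlets a single [boundarySpec()] or a list of them.
#' @param symmetrySides character vector of box sides treated as shear-free
#'   symmetry planes.
#' @return A [FlowDomain-class].
#' @export
buildFlowDomain <- function(pf, rf, inlets, outlets,
                            symmetrySides = character()) {
  if (!is.null(inlets$side)) inlets <- list(inlets)
  if (!is.null(outlets$side)) outlets <- list(outlets)
  mask <- !pf@solidMask
  assertThat(any(mask), "flow domain is empty after solidification")
  ## drop isolated fluid cells (no fluid neighbour along any axis)
  nb <- array(0L, dim(mask))
  for (ax in 1:3) for (s in c(-1L, 1L))
    nb <- nb + shift3(mask, ax, s, FALSE)
  iso <- mask & nb == 0L
  if (any(iso)) {
    message("reassigning ", sum(iso), " isolated fluid cell(s) to solid")
    mask[iso] <- FALSE
  }
  dom <- new("FlowDomain", fluidMask = mask, resistance = rf,
             spacing = pf@spacing, origin = pf@origin,
             inlets = inlets, outlets = outlets,
             symmetrySides = as.character(symmetrySides))
  ## validate that every spec selects at least one fluid-adjacent face
  for (spec in c(inlets, outlets)) {
    if (sum(sideFaceSelector(mask, spec)) == 0L)
      stop("boundary spec on side '", spec$side,
           "' selects no fluid-adjacent faces", call. = FALSE)
  }
  keepConnected(dom)
}

## logical array over the face grid of spec$side's axis marking selected
## exterior faces (fluid cell inside, domain boundary outside)
sideFaceSelector <- function(mask, spec) {
  d <- dim(mask)
  ax <- sideAxis(spec$side); hi <- sideHigh(spec$side)
  fd <- d; fd[ax] <- d[ax] + 1L
  sel <- array(FALSE, fd)
  idx <- lapply(d, seq_len)
  idx[[ax]] <- if (hi) d[ax] else 1L
  plane <- mask[idx[[1]], idx[[2]], idx[[3]]]  # fluid cells touching the side
  if (!is.null(spec$mask)) {
    tang <- setdiff(1:3, ax)
    assertThat(identical(dim(spec$mask), d[tang]),
               "boundary mask dimensions must match the tangential axes")
    plane <- plane & spec$mask
  }
  fidx <- idx
  fidx[[ax]] <- if (hi) d[ax] + 1L else 1L
  sel[fidx[[1]], fidx[[2]], fidx[[3]]] <- plane
  sel
}

## keep only fluid components connected to both an inlet and an outlet face
keepConnected <- function(dom) {
  mask <- dom@fluidMask
  seed <- array(FALSE, dim(mask))
  for (spec in dom@inlets) {
    ax <- sideAxis(spec$side); hi <- sideHigh(spec$side)
    sel <- sideFaceSelector(mask, spec)
    ## cell adjacent to each selected face
    d <- dim(mask); idx <- lapply(d, seq_len)
    fidx <- idx; fidx[[ax]] <- if (hi) d[ax] + 1L else 1L
    cidx <- idx; cidx[[ax]] <- if (hi) d[ax] else 1L
    pl <- sel[fidx[[1]], fidx[[2]], fidx[[3]]]
    sd <- seed[cidx[[1]], cidx[[2]], cidx[[3]]]
    seed[cidx[[1]], cidx[[2]], cidx[[3]]] <- sd | pl
  }
  ## flood fill from inlet-adjacent cells
  reach <- seed & mask
  repeat {
    grown <- reach
    for (ax in 1:3) for (s in c(-1L, 1L))
      grown <- grown | shift3(reach, ax, s, FALSE)
    grown <- grown & mask
    if (identical(grown, reach)) break
    reach <- grown
  }
  ## does the reachable set touch an outlet?
  touchesOutlet <- FALSE
  for (spec in dom@outlets)
    touchesOutlet <- touchesOutlet || sum(sideFaceSelector(reach, spec)) > 0L
  if (!touchesOutlet)
    stop("no fluid path connects the inlet(s) to the outlet(s); ",
         "net flux would be zero", call. = FALSE)
  dropped <- sum(mask & !reach)
  if (dropped > 0L) {
    message("removing ", dropped,
            " fluid cell(s) not connected to the inlet(s)")
    dom@fluidMask <- reach
  }
  dom
}

## Build stat/val arrays for one orientation.
## stat codes: 0 inactive, 1 interior unknown, 2 Dirichlet value,
##             3 wall (0), 4 outlet unknown, 5 symmetry (0)
faceArrays <- function(dom, ax, cfg) {
  mask <- dom@fluidMask
  d <- dim(mask)
  fd <- d; fd[ax] <- d[ax] + 1L
  L <- array(FALSE, fd); R <- array(FALSE, fd)
  idx <- lapply(fd, seq_len)
  li <- idx; li[[ax]] <- 2:fd[ax]
  ri <- idx; ri[[ax]] <- 1:d[ax]
  L[li[[1]], li[[2]], li[[3]]] <- mask
  R[ri[[1]], ri[[2]], ri[[3]]] <- mask
  stat <- array(0L, fd)
  stat[L & R] <- 1L
  stat[xor(L, R)] <- 3L
  val <- array(0, fd)
  ## symmetry sides normal to this orientation
  for (side in dom@symmetrySides) {
    if (sideAxis(side) != ax) next
    hi <- sideHigh(side)
    pidx <- lapply(fd, seq_len)
    pidx[[ax]] <- if (hi) fd[ax] else 1L
    pl <- stat[pidx[[1]], pidx[[2]], pidx[[3]]]
    pl[pl == 3L] <- 5L
    stat[pidx[[1]], pidx[[2]], pidx[[3]]] <- pl
  }
  ## inlets (Dirichlet) and outlets (unknown, ghost p = 0)
  applySpec <- function(spec, code) {
    if (sideAxis(spec$side) != ax) return()
    sel <- sideFaceSelector(mask, spec)
    if (code == 2L) {
      sgn <- if (sideHigh(spec$side)) -1 else 1
      if (!is.null(spec$profile)) {
        tang <- setdiff(1:3, ax)
        w <- which(sel, arr.ind = TRUE)
        t1 <- dom@origin[tang[1]] + dom@spacing[tang[1]] * (w[, tang[1]] - 1)
        t2 <- dom@origin[tang[2]] + dom@spacing[tang[2]] * (w[, tang[2]] - 1)
        val[sel] <<- sgn * spec$profile(t1, t2)
      } else {
        sp <- if (!is.null(spec$speed)) spec$speed else cfg$inletSpeed
        val[sel] <<- sgn * sp
      }
    }
    stat[sel] <<- code
  }
  for (spec in dom@inlets) applySpec(spec, 2L)
  for (spec in dom@outlets) applySpec(spec, 4L)
  list(stat = stat, val = val, fd = fd)
}

## label of a box side for tangential ghost handling:
## "mirror" (no-slip / prescribed velocity plane) adds 2 mu/h^2 to the
## diagonal, "free" (symmetry or outlet) drops the term
sideGhostLabels <- function(dom) {
  lab <- setNames(rep("mirror", 6L), SIDES)
  for (side in dom@symmetrySides) lab[side] <- "free"
  for (spec in dom@outlets) lab[spec$side] <- "free"
  lab
}

#' Solve steady creeping flow through a porous voxel domain
#'
#' Discretises the Stokes-Brinkman equations on the staggered voxel grid of
#' `domain` and solves the saddle-point system to the configured tolerance.
#' The system is linear: velocities and pressures scale proportionally with
#' the inlet speed.
#'
#' @param domain a [FlowDomain-class].
#' @param fluid a [FluidProps-class].
#' @param cfg a [solverConfig()] list.
#' @return A [FlowSolution-class]; `@info` holds the residuals and the
#'   mass-balance summary.
#' @export
solveCreepingFlow <- function(domain, fluid, cfg = solverConfig()) {
  mask <- domain@fluidMask
  d <- dim(mask)
  hmm <- isotropicSpacing(domain@spacing, "flow solve")
  h <- hmm * 1e-3  # metres
  mu <- fluid@mu
  Pv <- domain@resistance@Pv
  ghost <- sideGhostLabels(domain)

  fa <- lapply(1:3, faceArrays, dom = domain, cfg = cfg)
  ## unknown numbering, global across orientations
  nUn <- integer(3)
  idxA <- vector("list", 3)
  off <- 0L
  for (a in 1:3) {
    unknown <- fa[[a]]$stat == 1L | fa[[a]]$stat == 4L
    ids <- array(0L, fa[[a]]$fd)
    ids[unknown] <- seq_len(sum(unknown))
    nUn[a] <- sum(unknown)
    idxA[[a]] <- ids
    off <- off + nUn[a]
  }
  nU <- sum(nUn)
  cellIdx <- array(0L, d)
  cellIdx[mask] <- seq_len(sum(mask))
  nP <- sum(mask)
  assertThat(nU > 0 && nP > 0, "flow domain has no unknowns")

  muh2 <- mu / h^2
  dirOffsets <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                      c(0, 0, -1), c(0, 0, 1))
  dirSide <- c("x-", "x+", "y-", "y+", "z-", "z+")

  Ablocks <- vector("list", 3)
  bList <- vector("list", 3)
  Gtrip <- list(i = integer(0), j = integer(0), x = numeric(0))
  offs <- c(0L, cumsum(nUn))[1:3]

  for (a in 1:3) {
    st <- fa[[a]]$stat; vl <- fa[[a]]$val; fd <- fa[[a]]$fd
    ids <- idxA[[a]]
    F <- which(st == 1L | st == 4L)
    if (!length(F)) next
    w <- arrayInd(F, fd)
    myId <- ids[F]
    n <- length(F)
    diag <- numeric(n)
    rhs <- numeric(n)
    ti <- list(); tj <- list(); tx <- list()

    ## face resistance: mean of adjacent fluid-cell P_v
    cl <- w; cl[, a] <- cl[, a] - 1L   # left cell (may be outside)
    cr <- w                            # right cell (may be outside)
    inGrid <- function(cc) cc[, 1] >= 1 & cc[, 1] <= d[1] &
      cc[, 2] >= 1 & cc[, 2] <= d[2] & cc[, 3] >= 1 & cc[, 3] <= d[3]
    lin <- function(cc) cc[, 1] + d[1] * (cc[, 2] - 1L) +
      d[1] * d[2] * (cc[, 3] - 1L)
    okL <- inGrid(cl); okL[okL] <- mask[lin(cl[okL, , drop = FALSE])]
    okR <- inGrid(cr); okR[okR] <- mask[lin(cr[okR, , drop = FALSE])]
    PvL <- numeric(n); PvR <- numeric(n)
    PvL[okL] <- Pv[lin(cl[okL, , drop = FALSE])]
    PvR[okR] <- Pv[lin(cr[okR, , drop = FALSE])]
    nAdj <- okL + okR
    diag <- diag + (PvL + PvR) / pmax(nAdj, 1L)

    ## pressure coupling (+1/h right cell, -1/h left cell)
    if (any(okL)) {
      Gtrip$i <- c(Gtrip$i, offs[a] + myId[okL])
      Gtrip$j <- c(Gtrip$j, cellIdx[lin(cl[okL, , drop = FALSE])])
      Gtrip$x <- c(Gtrip$x, rep(-1 / h, sum(okL)))
    }
    if (any(okR)) {
      Gtrip$i <- c(Gtrip$i, offs[a] + myId[okR])
      Gtrip$j <- c(Gtrip$j, cellIdx[lin(cr[okR, , drop = FALSE])])
      Gtrip$x <- c(Gtrip$x, rep(1 / h, sum(okR)))
    }

    ## 7-point viscous stencil
    for (dir in 1:6) {
      nb <- sweep(w, 2, dirOffsets[dir, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= fd[1] & nb[, 2] >= 1 &
        nb[, 2] <= fd[2] & nb[, 3] >= 1 & nb[, 3] <= fd[3]
      nbLin <- nb[ok, 1] + fd[1] * (nb[ok, 2] - 1L) +
        fd[1] * fd[2] * (nb[ok, 3] - 1L)
      nbSt <- integer(n); nbSt[ok] <- st[nbLin]
      tangential <- dirOffsets[dir, a] == 0L
      ## out-of-grid neighbours: ghost by box-side label
      if (any(!ok)) {
        if (tangential) {
          extra <- if (ghost[dirSide[dir]] == "mirror") 2 * muh2 else 0
          diag[!ok] <- diag[!ok] + extra
        }
        ## normal direction out-of-grid: outlet zero-gradient ghost (drop);
        ## only reachable from outlet faces at the box side
      }
      isUn <- ok & (nbSt == 1L | nbSt == 4L)
      isKn <- ok & nbSt == 2L
      isZero <- ok & (nbSt == 3L | nbSt == 5L)
      isInact <- ok & nbSt == 0L
      if (any(isUn)) {
        diag[isUn] <- diag[isUn] + muh2
        ti[[length(ti) + 1L]] <- myId[isUn]
        nbl <- nb[isUn, 1] + fd[1] * (nb[isUn, 2] - 1L) +
          fd[1] * fd[2] * (nb[isUn, 3] - 1L)
        tj[[length(tj) + 1L]] <- ids[nbl]
        tx[[length(tx) + 1L]] <- rep(-muh2, sum(isUn))
      }
      if (any(isKn)) {
        diag[isKn] <- diag[isKn] + muh2
        nbl <- nb[isKn, 1] + fd[1] * (nb[isKn, 2] - 1L) +
          fd[1] * fd[2] * (nb[isKn, 3] - 1L)
        rhs[isKn] <- rhs[isKn] + muh2 * vl[nbl]
      }
      if (any(isZero)) diag[isZero] <- diag[isZero] + muh2
      if (any(isInact)) {
        if (tangential) {
          ## wall surface halfway to the inactive row: mirror ghost
          diag[isInact] <- diag[isInact] + 2 * muh2
        }
        ## normal-direction inactive neighbour cannot occur for interior
        ## faces; for outlet faces the outward ghost is zero-gradient (drop)
      }
    }
    Ablocks[[a]] <- Matrix::sparseMatrix(
      i = c(myId, unlist(ti)), j = c(myId, unlist(tj)),
      x = c(diag, unlist(tx)), dims = c(nUn[a], nUn[a]))
    bList[[a]] <- rhs
  }

  G <- Matrix::sparseMatrix(i = Gtrip$i, j = Gtrip$j, x = Gtrip$x,
                            dims = c(nU, nP))
  b <- unlist(bList[!vapply(bList, is.null, TRUE)])
  if (is.null(b)) b <- numeric(nU)

  ## continuity rhs from known faces: g_c = -sum(signed known velocities)
  g <- numeric(nP)
  for (a in 1:3) {
    st <- fa[[a]]$stat; vl <- fa[[a]]$val; fd <- fa[[a]]$fd
    kn <- which(st == 2L & vl != 0)
    if (!length(kn)) next
    w <- arrayInd(kn, fd)
    ## high-side cell (face is its low face, sign -1)
    cr <- w
    okR <- cr[, a] <= d[a]
    if (any(okR)) {
      cc <- cr[okR, , drop = FALSE]
      li <- cc[, 1] + d[1] * (cc[, 2] - 1L) + d[1] * d[2] * (cc[, 3] - 1L)
      fluidR <- mask[li]
      tgt <- cellIdx[li[fluidR]]
      g[tgt] <- g[tgt] + vl[kn][okR][fluidR]   # -(-1)*val
    }
    ## low-side cell (face is its high face, sign +1)
    cl <- w; cl[, a] <- cl[, a] - 1L
    okL <- cl[, a] >= 1L
    if (any(okL)) {
      cc <- cl[okL, , drop = FALSE]
      li <- cc[, 1] + d[1] * (cc[, 2] - 1L) + d[1] * d[2] * (cc[, 3] - 1L)
      fluidL <- mask[li]
      tgt <- cellIdx[li[fluidL]]
      g[tgt] <- g[tgt] - vl[kn][okL][fluidL]   # -(+1)*val
    }
  }

  ## sparse LU fill-in makes the direct saddle solve practical only for
  ## small or effectively 2-D domains; the Schur CG handles the rest
  method <- cfg$method
  if (method == "auto") {
    small <- nU + nP <= cfg$directMaxUnknowns
    flat <- min(d) == 1L
    method <- if (small && flat) "direct" else "schur"
  }

  sol <- if (method == "direct")
    solveSaddleDirect(Ablocks, G, b, g, h, nUn)
  else
    solveSaddleSchur(Ablocks, G, b, g, h, nUn, cfg)

  assembleSolution(domain, fa, idxA, cellIdx, sol, h, cfg, method)
}

solveSaddleDirect <- function(Ablocks, G, b, g, h, nUn) {
  A <- Matrix::bdiag(Ablocks[nUn > 0])
  nU <- nrow(G); nP <- ncol(G)
  K <- rbind(cbind(A, G),
             cbind(Matrix::t(G), Matrix::sparseMatrix(i = integer(0),
               j = integer(0), x = numeric(0), dims = c(nP, nP))))
  rhs <- c(b, -g / h)
  x <- as.numeric(Matrix::solve(K, rhs, sparse = TRUE))
  list(u = x[seq_len(nU)], p = x[nU + seq_len(nP)], iterations = 1L,
       relResidual = 0)
}

## CG on the pressure Schur complement S = G' A^-1 G with Jacobi
## preconditioning; A blocks are Cholesky-factored once
solveSaddleSchur <- function(Ablocks, G, b, g, h, nUn, cfg) {
  keep <- which(nUn > 0)
  chol <- lapply(keep, function(a) Matrix::Cholesky(Ablocks[[a]], LDL = FALSE))
  offs <- c(0L, cumsum(nUn))
  Ainv <- function(x) {
    out <- numeric(length(x))
    for (k in seq_along(keep)) {
      a <- keep[k]
      rng <- (offs[a] + 1L):offs[a + 1L]
      out[rng] <- as.numeric(Matrix::solve(chol[[k]], x[rng], system = "A"))
    }
    out
  }
  Smv <- function(p) as.numeric(Matrix::crossprod(G, Ainv(as.numeric(G %*% p))))
  rhs <- as.numeric(Matrix::crossprod(G, Ainv(b))) + g / h
  nP <- ncol(G)
  ## Jacobi preconditioner: diag(S) ~ sum_f G_fc^2 / A_ff
  Adiag <- unlist(lapply(keep, function(a) Matrix::diag(Ablocks[[a]])))
  G2 <- G; G2@x <- G2@x^2 / Adiag[G2@i + 1L]
  dS <- as.numeric(Matrix::colSums(G2))
  dS[dS <= 0] <- 1
  p <- numeric(nP)
  r <- rhs
  rn0 <- sqrt(sum(r^2))
  if (rn0 == 0)
    return(list(u = Ainv(b), p = p, iterations = 0L, relResidual = 0))
  z <- r / dS
  q <- z
  rz <- sum(r * z)
  it <- 0L
  repeat {
    it <- it + 1L
    Sq <- Smv(q)
    alpha <- rz / sum(q * Sq)
    p <- p + alpha * q
    r <- r - alpha * Sq
    rn <- sqrt(sum(r^2))
    if (rn / rn0 <= cfg$tol || it >= cfg$maxIter) break
    z <- r / dS
    rzNew <- sum(r * z)
    beta <- rzNew / rz
    rz <- rzNew
    q <- z + beta * q
  }
  if (rn / rn0 > cfg$tol)
    stop("pressure Schur CG did not converge: relative residual ",
         signif(rn / rn0, 3), " after ", it, " iterations", call. = FALSE)
  u <- Ainv(b - as.numeric(G %*% p))
  list(u = u, p = p, iterations = it, relResidual = rn / rn0)
}

assembleSolution <- function(domain, fa, idxA, cellIdx, sol, h, cfg, method) {
  mask <- domain@fluidMask
  d <- dim(mask)
  vel <- vector("list", 3)
  off <- 0L
  for (a in 1:3) {
    st <- fa[[a]]$stat; vl <- fa[[a]]$val
    out <- vl
    un <- st == 1L | st == 4L
    nUn <- sum(un)
    if (nUn) out[un] <- sol$u[off + idxA[[a]][un]]
    off <- off + nUn
    vel[[a]] <- out
  }
  p <- array(NA_real_, d)
  p[mask] <- sol$p
  speed <- cellSpeed(vel, mask)
  mb <- massBalance(domain, vel, h)
  info <- list(method = method, iterations = sol$iterations,
               relResidual = sol$relResidual,
               inletFlux = mb$inletFlux, outletFlux = mb$outletFlux,
               maxCellDivergence = mb$maxCellDivergence)
  new("FlowSolution", u = vel[[1]], v = vel[[2]], w = vel[[3]],
      pressure = p, speed = speed, fluidMask = mask,
      spacing = domain@spacing, origin = domain@origin, info = info)
}

cellSpeed <- function(vel, mask) {
  d <- dim(mask)
  comp2 <- array(0, d)
  for (a in 1:3) {
    f <- vel[[a]]
    loIdx <- lapply(dim(f), seq_len); loIdx[[a]] <- 1:d[a]
    hiIdx <- lapply(dim(f), seq_len); hiIdx[[a]] <- 2:(d[a] + 1L)
    cc <- (f[loIdx[[1]], loIdx[[2]], loIdx[[3]], drop = FALSE] +
           f[hiIdx[[1]], hiIdx[[2]], hiIdx[[3]], drop = FALSE]) / 2
    comp2 <- comp2 + array(cc, d)^2
  }
  sp <- sqrt(comp2)
  sp[!mask] <- 0
  sp
}

#' Cell-centred speed field of a flow solution
#'
#' Averages opposing face-normal velocity components to cell centres and
#' returns the Euclidean magnitude; zero on solid voxels.
#'
#' @param x a [FlowSolution-class].
#' @return A 3-D array of |v_s|, m s^-1.
#' @export
setMethod("speedField", "FlowSolution", function(x) x@speed)

massBalance <- function(domain, vel, h) {
  mask <- domain@fluidMask
  inFlux <- 0; outFlux <- 0
  for (spec in domain@inlets) {
    a <- sideAxis(spec$side); hi <- sideHigh(spec$side)
    sel <- sideFaceSelector(mask, spec)
    sgn <- if (hi) -1 else 1
    inFlux <- inFlux + sgn * sum(vel[[a]][sel]) * h^2
  }
  for (spec in domain@outlets) {
    a <- sideAxis(spec$side); hi <- sideHigh(spec$side)
    sel <- sideFaceSelector(mask, spec)
    sgn <- if (hi) 1 else -1
    outFlux <- outFlux + sgn * sum(vel[[a]][sel]) * h^2
  }
  ## discrete divergence per fluid cell
  d <- dim(mask)
  div <- array(0, d)
  for (a in 1:3) {
    f <- vel[[a]]
    loIdx <- lapply(dim(f), seq_len); loIdx[[a]] <- 1:d[a]
    hiIdx <- lapply(dim(f), seq_len); hiIdx[[a]] <- 2:(d[a] + 1L)
    div <- div + (array(f[hiIdx[[1]], hiIdx[[2]], hiIdx[[3]], drop = FALSE], d) -
                  array(f[loIdx[[1]], loIdx[[2]], loIdx[[3]], drop = FALSE], d)) / h
  }
  div[!mask] <- 0
  list(inletFlux = inFlux, outletFlux = outFlux,
       maxCellDivergence = max(abs(div)))
}

#' Mass-balance report of a converged solution
#'
#' @param sol a [FlowSolution-class].
#' @param domain the [FlowDomain-class] it was solved on.
#' @return A list with `inletFlux`, `outletFlux` (m^3 s^-1),
#'   `relativeImbalance` and `maxCellDivergence` (s^-1).
#' @export
massBalanceReport <- function(sol, domain) {
  h <- isotropicSpacing(domain@spacing) * 1e-3
  mb <- massBalance(domain, list(sol@u, sol@v, sol@w), h)
  rel <- if (mb$inletFlux != 0)
    abs(mb$inletFlux - mb$outletFlux) / abs(mb$inletFlux) else 0
  c(mb, list(relativeImbalance = rel))
}
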