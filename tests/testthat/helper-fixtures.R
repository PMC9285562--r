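## shared fixture builders (all generated in code; no stored data)

uniformPorosityField <- function(dims, eps = 1, spacingMm = 0.1,
                                 epsMin = 0.1) {
  new("PorosityField", epsilon = array(eps, dims),
      solidMask = array(FALSE, dims), spacing = rep(spacingMm, 3L),
      origin = c(0, 0, 0), epsMin = epsMin)
}

zeroResistanceField <- function(dims, spacingMm = 0.1) {
  new("ResistanceField", Pv = array(0, dims), Pi = array(0, dims),
      d = spacingMm * 1e-3, spacing = rep(spacingMm, 3L),
      origin = c(0, 0, 0))
}

## fully developed rectangular-duct profile (series solution), duct
## cross-section a x b, pressure gradient G, viscosity mu
ductSeriesProfile <- function(y, z, a, b, G, mu, nterms = 81) {
  u <- 0
  for (n in seq(1, nterms, 2))
    u <- u + (1 / n^3) *
      (1 - cosh(n * pi * (z - b / 2) / a) / cosh(n * pi * b / (2 * a))) *
      sin(n * pi * y / a)
  4 * G * a^2 / (mu * pi^3) * u
}

## radially symmetric decreasing field exp(-r^2) on an n^3 grid over
## [-1, 1]^3
radialGaussianField <- function(n = 48L) {
  sp <- 2 / (n - 1)
  x <- (seq_len(n) - 1) * sp - 1
  f <- array(0, c(n, n, n))
  for (k in seq_len(n))
    f[, , k] <- outer(x, x, function(a, b) exp(-(a^2 + b^2 + x[k]^2)))
  list(f = f, spacing = sp, origin = c(-1, -1, -1))
}

## iso-surface sphere of radius R from the analytic radial field
sphereMesh <- function(R, n = 64L, extent = 2) {
  sp <- 2 * extent / (n - 1)
  x <- (seq_len(n) - 1) * sp - extent
  f <- array(0, c(n, n, n))
  for (k in seq_len(n))
    f[, , k] <- outer(x, x, function(a, b) -sqrt(a^2 + b^2 + x[k]^2))
  extractIsosurface(f + 2 * extent, 2 * extent - R, spacing = sp,
                    origin = rep(-extent, 3))
}
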