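# TG43-U1 dose-rate formalism: geometry factor for a line source, radial
# dose function, anisotropy-table interpolation and the assembled dose rate.

.SIN_EPS <- 1e-9   # below this, sin(theta) is treated as 0 (polar axis branch)

#' Convert bench coordinates to source-centred polar coordinates
#'
#' During phantom scans the source travels along the z axis while the sensor
#' sits at a fixed transverse distance `y` (at `zSensor` on the same axis).
#' This maps each geometry to the distance `r` and the polar angle `theta`
#' measured from the source long axis (the z axis).
#'
#' The sign convention is `theta = atan2(y, -(zSource - zSensor))`: a source
#' displaced towards positive z relative to the sensor gives `theta > pi/2`,
#' negative z gives `theta < pi/2`, and `theta = pi/2` on the transverse
#' plane. Only the symmetry about `pi/2` matters physically; the mapping is
#' fixed so that signed bench data are reproducible.
#'
#' @param y transverse sensor distance(s), cm; must be positive.
#' @param zSource source position(s) along z, cm.
#' @param zSensor sensor position along z, cm (default 0).
#' @return A [PolarPoint-class] with `r = sqrt(y^2 + dz^2)`.
#' @examples
#' yzToPolar(2, 0)            # r = 2 cm on the transverse plane
#' yzToPolar(3, -4)@r         # 5 (3-4-5 triangle)
#' @export
yzToPolar <- function(y, zSource, zSensor = 0) {
  if (any(y <= 0))
    stop("invalid geometry: the transverse distance y must be positive")
  dz <- zSource - zSensor
  polarPoint(r = sqrt(y^2 + dz^2), theta = atan2(y, -dz))
}

# endpoint construction of the subtended angle; sensor at (r sin, r cos),
# source endpoints on the z axis at +/- L/2
.betaFromEndpoints <- function(r, theta, L) {
  sy <- r * sin(theta)
  sz <- r * cos(theta)
  v1 <- rbind(0 - sy, L / 2 - sz)
  v2 <- rbind(0 - sy, -L / 2 - sz)
  num <- colSums(v1 * v2)
  den <- sqrt(colSums(v1^2) * colSums(v2^2))
  acos(pmin(1, pmax(-1, num / den)))
}

#' Angle subtended by the source at the sensor
#'
#' `beta` is the angle, seen from the sensor, between the two endpoints of
#' the active source segment of length `L` centred at the origin and
#' oriented along the source axis (the difference of the two endpoint
#' angles in the TG-43 line-source geometry).
#'
#' @param p a [PolarPoint-class], or a numeric vector of radii (cm) when
#'   `theta` is given.
#' @param L active source length, cm.
#' @param theta polar angle(s), radians; ignored when `p` is a `PolarPoint`.
#' @return Subtended angle(s) in radians, in \[0, pi).
#' @examples
#' betaAngle(polarPoint(0.7, pi / 2), L = 0.35)  # 2*atan(L / (2 r))
#' @export
betaAngle <- function(p, L, theta = NULL) {
  if (is(p, "PolarPoint")) { r <- p@r; theta <- p@theta }
  else r <- as.numeric(p)
  if (L < 0) stop("source length L must be >= 0")
  if (any(r <= L / 2))
    stop("sensor inside the source: r must exceed L/2")
  if (L == 0) return(rep(0, length(r)))
  .betaFromEndpoints(r, theta, L)
}

#' TG-43 line-source geometry factor
#'
#' \deqn{G(r,\theta) = \beta / (L r \sin\theta)} away from the source axis,
#' \deqn{G(r,0) = (r^2 - L^2/4)^{-1}} on the axis (and at \eqn{\theta=\pi}
#' by symmetry), and \eqn{1/r^2} for a point source (`L = 0`). Units: 1/cm^2
#' with `r`, `L` in cm.
#'
#' The axial branch is taken whenever \eqn{\sin\theta < 10^{-9}} to avoid
#' the division blow-up at the pole.
#'
#' @inheritParams betaAngle
#' @return Geometry factor(s), 1/cm^2.
#' @examples
#' geometryFactor(polarPoint(0.7, pi / 2), L = 0.35)  # within 5% of 1/r^2
#' geometryFactor(polarPoint(2, pi / 2), L = 0)       # 0.25
#' @export
geometryFactor <- function(p, L, theta = NULL) {
  if (is(p, "PolarPoint")) { r <- p@r; theta <- p@theta }
  else r <- as.numeric(p)
  if (L < 0) stop("source length L must be >= 0")
  if (any(r <= L / 2))
    stop("sensor inside the source: r must exceed L/2")
  if (L == 0) return(1 / r^2)
  axial <- sin(theta) < .SIN_EPS
  g <- numeric(length(r))
  if (any(axial)) g[axial] <- 1 / (r[axial]^2 - L^2 / 4)
  if (any(!axial)) {
    b <- .betaFromEndpoints(r[!axial], theta[!axial], L)
    g[!axial] <- b / (L * r[!axial] * sin(theta[!axial]))
  }
  g
}

#' Radial dose function
#'
#' Heuristic parametrisation of the in-medium radial dose fall-off of a
#' cylindrical source:
#' \deqn{g(r) = \Big(\sum_{n=-2}^{3} a_n r^n\Big)\, e^{-a_e r},}
#' a Laurent polynomial multiplied by a single exponential attenuation
#' factor. Coefficients are source- and afterloader-specific configuration;
#' TG-43 normalisation requires \eqn{g(r_0) = 1}.
#'
#' @param r radial distance(s), cm; must be positive.
#' @param coeffs the six coefficients \eqn{a_n} in the order
#'   \eqn{n = -2, -1, 0, 1, 2, 3}.
#' @param aE exponential decay constant \eqn{a_e}, 1/cm.
#' @return Dimensionless g(r).
#' @examples
#' radialDoseFunction(3, c(0, 0, 0, 1, 0, 0), 0)  # pure linear term: 3
#' @export
radialDoseFunction <- function(r, coeffs, aE = 0) {
  if (any(r <= 0)) stop("radial dose function is defined for r > 0 only")
  if (length(coeffs) != 6L)
    stop("coeffs must hold the 6 coefficients a_n for n = -2..3")
  powers <- -2:3
  poly <- rowSums(outer(r, powers, `^`) *
                    matrix(coeffs, nrow = length(r), ncol = 6, byrow = TRUE))
  poly * exp(-aE * r)
}

# bilinear interpolation on the (r, theta-degree) grid, clamping out-of-hull
# queries to the nearest edge
.bilinear <- function(tab, r, thetaDeg, warn = TRUE) {
  rg <- tab@rGrid; tg <- tab@thetaGrid
  out <- r < rg[1] | r > rg[length(rg)] |
    thetaDeg < tg[1] | thetaDeg > tg[length(tg)]
  if (warn && any(out))
    warning(sprintf("%d anisotropy quer%s outside the table hull: clamped to the nearest edge",
                    sum(out), if (sum(out) == 1) "y lies" else "ies lie"),
            call. = FALSE)
  r <- pmin(pmax(r, rg[1]), rg[length(rg)])
  thetaDeg <- pmin(pmax(thetaDeg, tg[1]), tg[length(tg)])
  i <- pmin(pmax(findInterval(r, rg), 1L), length(rg) - 1L)
  j <- pmin(pmax(findInterval(thetaDeg, tg), 1L), length(tg) - 1L)
  fr <- (r - rg[i]) / (rg[i + 1L] - rg[i])
  ft <- (thetaDeg - tg[j]) / (tg[j + 1L] - tg[j])
  v <- tab@values
  n <- length(r)
  idx <- cbind(rep(i, length.out = n), rep(j, length.out = n))
  (1 - fr) * (1 - ft) * v[idx] +
    fr * (1 - ft) * v[idx + matrix(c(1L, 0L), n, 2, byrow = TRUE)] +
    (1 - fr) * ft * v[idx + matrix(c(0L, 1L), n, 2, byrow = TRUE)] +
    fr * ft * v[idx + matrix(c(1L, 1L), n, 2, byrow = TRUE)]
}

#' Anisotropy factor from a look-up table
#'
#' Bilinear interpolation of \eqn{F(r, \theta)} on the table's
#' (r, theta-in-degrees) grid; exact at grid nodes and linear between them.
#' Queries outside the table hull are clamped to the nearest edge with a
#' warning (published tables rarely cover very small radii). In
#' point-source mode (`table = "point"`) the factor is identically 1.
#'
#' @param p a [PolarPoint-class], or numeric radii (cm) with `theta` given.
#' @param table an [AnisotropyTable-class], or the string `"point"`.
#' @param theta polar angle(s), radians; ignored when `p` is a `PolarPoint`.
#' @return Interpolated anisotropy factor(s).
#' @export
anisotropyFactor <- function(p, table, theta = NULL) {
  if (is(p, "PolarPoint")) { r <- p@r; theta <- p@theta }
  else r <- as.numeric(p)
  if (is.character(table)) {
    if (!identical(table, .POINT_SOURCE))
      stop("configuration error: table must be an AnisotropyTable or \"point\"")
    return(rep(1, length(r)))
  }
  if (!is(table, "AnisotropyTable"))
    stop("configuration error: table must be an AnisotropyTable or \"point\"")
  .bilinear(table, r, theta * 180 / pi)
}

#' TG43-U1 dose rate
#'
#' The full protocol product
#' \deqn{\dot D(r, \theta) = s_k\, \Lambda\, F(r,\theta)\,
#'   \frac{G(r,\theta)}{G(r_0,\theta_0)}\, g(r),}
#' with the geometry factor normalised at the source's reference point
#' \eqn{(r_0, \theta_0)}. With \eqn{g(r_0) = 1} and \eqn{F(r_0,\theta_0)=1}
#' the dose rate at the reference point is exactly
#' \eqn{s_k \Lambda}.
#'
#' @param p a [PolarPoint-class], or numeric radii (cm) with `theta` given.
#' @param src a [SourceSpec-class].
#' @param theta polar angle(s), radians; ignored when `p` is a `PolarPoint`.
#' @return Dose rate(s) in the dose-per-hour units implied by
#'   `airKermaStrength * doseRateConstant`.
#' @examples
#' src <- sourceSpec(airKermaStrength = 4e4, doseRateConstant = 1.109)
#' doseRate(polarPoint(2, pi / 2), src)   # s_k * Lambda at the reference
#' @export
doseRate <- function(p, src, theta = NULL) {
  if (!is(p, "PolarPoint")) p <- polarPoint(as.numeric(p), theta)
  L <- src@capsuleLength
  G <- geometryFactor(p, L)
  G0 <- geometryFactor(polarPoint(src@r0, src@theta0), L)
  g <- radialDoseFunction(p@r, src@radialCoeffs, src@radialDecay)
  F <- anisotropyFactor(p, src@anisotropy)
  src@airKermaStrength * src@doseRateConstant * F * (G / G0) * g
}
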