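# Synthetic study-condition sources. Consensus radial-dose and anisotropy
# parameters for specific commercial sources are licensed look-up data and
# are not shipped; these constructors build physically plausible synthetic
# stand-ins with the right magnitudes, used throughout the examples, tests
# and simulations.

#' Synthetic HDR and LDR study sources
#'
#' `exampleHdrSource()` emulates a ~4.8 Ci Ir-192 HDR source: air-kerma
#' strength 1.97e4 U, dose-rate constant 1.109 cGy/(h U), capsule length
#' 3.6 mm, a mild polynomial radial dose function normalised at the 2 cm
#' reference, and a synthetic anisotropy table dipping towards the source
#' axis. `exampleLdrSource()` emulates a 0.3 mCi I-125 seed: air-kerma
#' strength 0.38 U, dose-rate constant 0.965 cGy/(h U) at the
#' protocol-standard 1 cm reference of low-dose-rate seeds, treated as a
#' point source with a strongly attenuated radial dose function
#' (\eqn{a_e = 0.35} per cm, halving roughly every 2 cm as low-energy
#' photons do in water).
#'
#' @param anisotropy for the HDR source: an [AnisotropyTable-class], the
#'   string `"point"`, or `NULL` (default) for the built-in synthetic
#'   table.
#' @return A [SourceSpec-class].
#' @examples
#' doseRate(polarPoint(2, pi / 2), exampleHdrSource())  # s_k * Lambda
#' @export
exampleHdrSource <- function(anisotropy = NULL) {
  if (is.null(anisotropy)) anisotropy <- syntheticAnisotropy()
  # g(r) = (a0 + 0.01 r - 0.002 r^2) exp(-0.0025 r) with g(2) = 1
  a0 <- exp(0.005) - 0.02 + 0.008
  sourceSpec(airKermaStrength = 1.97e4, doseRateConstant = 1.109,
             capsuleLength = 0.36,
             radialCoeffs = c(0, 0, a0, 0.01, -0.002, 0),
             radialDecay = 0.0025, anisotropy = anisotropy,
             r0 = 2, theta0 = pi / 2)
}

#' @rdname exampleHdrSource
#' @export
exampleLdrSource <- function() {
  # g(r) = a0 exp(-0.35 r) with g(1) = 1
  sourceSpec(airKermaStrength = 0.38, doseRateConstant = 0.965,
             capsuleLength = 0,
             radialCoeffs = c(0, 0, exp(0.35), 0, 0, 0),
             radialDecay = 0.35, anisotropy = "point",
             r0 = 1, theta0 = pi / 2)
}

#' Synthetic anisotropy table
#'
#' A smooth stand-in for a consensus anisotropy look-up table:
#' \eqn{F(r, \theta) = 1 - c(r) \cos^2\theta} with the axial dip
#' \eqn{c(r) = 0.25 - 0.015 r} relaxing with distance, exactly 1 on the
#' transverse plane as the TG-43 convention requires.
#'
#' @param rGrid radial grid, cm.
#' @param thetaGrid angular grid, degrees.
#' @return An [AnisotropyTable-class].
#' @export
syntheticAnisotropy <- function(rGrid = c(0.5, 1, 2, 3, 5, 8, 12),
                                thetaGrid = seq(0, 180, by = 10)) {
  dip <- pmax(0.05, 0.25 - 0.015 * rGrid)
  values <- outer(dip, cos(thetaGrid * pi / 180)^2,
                  function(d, c2) 1 - d * c2)
  anisotropyTable(rGrid, thetaGrid, values)
}
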