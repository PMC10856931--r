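#' @import methods
NULL

.POINT_SOURCE <- "point"

#' Anisotropy look-up table
#'
#' Two-dimensional grid of the TG43-U1 anisotropy factor \eqn{F(r, \theta)},
#' as published in consensus look-up tables for encapsulated brachytherapy
#' sources. The table is queried by bilinear interpolation via
#' [anisotropyFactor()].
#'
#' @slot rGrid numeric, radial grid in cm, strictly increasing.
#' @slot thetaGrid numeric, polar-angle grid in degrees within \[0, 180\],
#'   strictly increasing (angle measured from the source long axis).
#' @slot values numeric matrix of positive factors, rows indexed by `rGrid`,
#'   columns by `thetaGrid`. By TG-43 convention \eqn{F(r, 90^\circ) = 1}.
#'
#' @seealso [anisotropyTable()], [anisotropyFactor()], [readAnisotropy()]
#' @export
setClass("AnisotropyTable",
  slots = c(rGrid = "numeric", thetaGrid = "numeric", values = "matrix"))

setValidity("AnisotropyTable", function(object) {
  msg <- character()
  if (length(object@rGrid) < 2L || length(object@thetaGrid) < 2L)
    msg <- c(msg, "rGrid and thetaGrid must each have at least 2 points")
  if (any(diff(object@rGrid) <= 0))
    msg <- c(msg, "rGrid must be strictly increasing with no duplicates")
  if (any(diff(object@thetaGrid) <= 0))
    msg <- c(msg, "thetaGrid must be strictly increasing with no duplicates")
  if (any(object@thetaGrid < 0) || any(object@thetaGrid > 180))
    msg <- c(msg, "thetaGrid must lie within [0, 180] degrees")
  if (any(object@rGrid <= 0))
    msg <- c(msg, "rGrid must be positive")
  if (!all(dim(object@values) == c(length(object@rGrid), length(object@thetaGrid))))
    msg <- c(msg, "values must be a length(rGrid) x length(thetaGrid) matrix")
  else if (any(!is.finite(object@values)) || any(object@values <= 0))
    msg <- c(msg, "all anisotropy values must be finite and positive")
  if (length(msg)) msg else TRUE
})

#' Construct an anisotropy table
#'
#' @param rGrid radial grid (cm), strictly increasing.
#' @param thetaGrid polar-angle grid (degrees in \[0, 180\]), strictly
#'   increasing.
#' @param values matrix of \eqn{F(r,\theta)} values
#'   (`length(rGrid)` x `length(thetaGrid)`).
#'
#' @details A warning is emitted when the interpolated transverse-plane row
#' \eqn{F(r, 90^\circ)} deviates from unity by more than 2\%, since TG-43
#' tables are normalised on the transverse plane.
#'
#' @return An [AnisotropyTable-class] object.
#' @examples
#' tab <- anisotropyTable(c(1, 2), c(0, 90, 180),
#'                        matrix(c(0.8, 0.8, 1, 1, 0.8, 0.8), nrow = 2))
#' @export
anisotropyTable <- function(rGrid, thetaGrid, values) {
  obj <- new("AnisotropyTable", rGrid = as.numeric(rGrid),
             thetaGrid = as.numeric(thetaGrid),
             values = matrix(as.numeric(values), nrow = length(rGrid)))
  if (min(obj@thetaGrid) <= 90 && max(obj@thetaGrid) >= 90) {
    f90 <- vapply(obj@rGrid, function(r)
      .bilinear(obj, r, 90, warn = FALSE), numeric(1))
    if (max(abs(f90 - 1)) > 0.02)
      warning("anisotropy table deviates from F(r, 90 deg) = 1 by more than 2%",
              call. = FALSE)
  }
  obj
}

setClassUnion("AnisotropyOrPoint", c("AnisotropyTable", "character"))

#' TG43-U1 source description
#'
#' Everything the dose-rate model needs to know about an encapsulated
#' brachytherapy source: the strength normalisation (air-kerma strength
#' \eqn{s_k} and dose-rate constant \eqn{\Lambda}), the active length of the
#' capsule, the radial-dose-function parametrisation, and either an
#' anisotropy look-up table or the point-source convention
#' (\eqn{F \equiv 1}).
#'
#' @slot airKermaStrength \eqn{s_k}, in dose units \eqn{\cdot} cm\eqn{^2}/h.
#' @slot doseRateConstant \eqn{\Lambda}, dose rate at the reference point per
#'   unit \eqn{s_k}.
#' @slot capsuleLength active source length \eqn{L} in cm (0 for a point
#'   source).
#' @slot radialCoeffs named numeric of length 6, polynomial coefficients
#'   \eqn{a_n} for \eqn{n = -2, \dots, 3} of the radial dose function.
#' @slot radialDecay exponential decay constant \eqn{a_e} in cm\eqn{^{-1}}.
#' @slot anisotropy an [AnisotropyTable-class] or the string `"point"`.
#' @slot r0,theta0 reference point: radius in cm (default 2) and angle in
#'   radians (default \eqn{\pi/2}, the transverse plane).
#'
#' @seealso [sourceSpec()], [doseRate()], [radialDoseFunction()]
#' @export
setClass("SourceSpec",
  slots = c(airKermaStrength = "numeric", doseRateConstant = "numeric",
            capsuleLength = "numeric", radialCoeffs = "numeric",
            radialDecay = "numeric", anisotropy = "AnisotropyOrPoint",
            r0 = "numeric", theta0 = "numeric"))

setValidity("SourceSpec", function(object) {
  msg <- character()
  if (object@airKermaStrength <= 0) msg <- c(msg, "airKermaStrength must be > 0")
  if (object@doseRateConstant <= 0) msg <- c(msg, "doseRateConstant must be > 0")
  if (object@capsuleLength < 0) msg <- c(msg, "capsuleLength must be >= 0")
  if (length(object@radialCoeffs) != 6L)
    msg <- c(msg, "radialCoeffs must hold the 6 coefficients a_n, n = -2..3")
  if (object@r0 <= object@capsuleLength / 2)
    msg <- c(msg, "reference radius r0 must exceed capsuleLength/2")
  if (object@theta0 < 0 || object@theta0 > pi)
    msg <- c(msg, "theta0 must lie in [0, pi]")
  if (is.character(object@anisotropy) &&
      !identical(object@anisotropy, .POINT_SOURCE))
    msg <- c(msg, "anisotropy must be an AnisotropyTable or the string \"point\"")
  if (length(msg)) msg else TRUE
})

#' Construct a TG43-U1 source specification
#'
#' @param airKermaStrength air-kerma strength \eqn{s_k} (dose units cm^2/h).
#' @param doseRateConstant dose-rate constant \eqn{\Lambda}.
#' @param capsuleLength active length \eqn{L} in cm; 0 denotes a point source.
#' @param radialCoeffs the six polynomial coefficients \eqn{a_n},
#'   \eqn{n = -2, \dots, 3}, of the radial dose function (see
#'   [radialDoseFunction()]). Default: \eqn{g \equiv 1}.
#' @param radialDecay exponential constant \eqn{a_e} (1/cm), default 0.
#' @param anisotropy [AnisotropyTable-class] object or `"point"` (default).
#' @param r0,theta0 reference point, default 2 cm on the transverse plane
#'   (\eqn{\theta_0 = \pi/2}).
#'
#' @details A warning is emitted when the supplied radial dose function does
#' not evaluate to 1 at the reference radius (TG-43 normalisation); the input
#' is kept as given, never silently renormalised.
#'
#' @return A [SourceSpec-class] object.
#' @examples
#' src <- sourceSpec(airKermaStrength = 4e4, doseRateConstant = 1.109,
#'                   capsuleLength = 0.36)
#' @export
sourceSpec <- function(airKermaStrength, doseRateConstant,
                       capsuleLength = 0,
                       radialCoeffs = c(0, 0, 1, 0, 0, 0),
                       radialDecay = 0,
                       anisotropy = .POINT_SOURCE,
                       r0 = 2, theta0 = pi / 2) {
  radialCoeffs <- as.numeric(radialCoeffs)
  names(radialCoeffs) <- paste0("a", -2:3)
  obj <- new("SourceSpec", airKermaStrength = airKermaStrength,
             doseRateConstant = doseRateConstant,
             capsuleLength = capsuleLength, radialCoeffs = radialCoeffs,
             radialDecay = radialDecay, anisotropy = anisotropy,
             r0 = r0, theta0 = theta0)
  g0 <- radialDoseFunction(r0, radialCoeffs, radialDecay)
  if (abs(g0 - 1) > 0.01)
    warning(sprintf("radial dose function g(r0 = %g cm) = %.4f, not 1: check the coefficients",
                    r0, g0), call. = FALSE)
  obj
}

#' Points in source-centred polar coordinates
#'
#' A vector of sensor positions expressed as distance `r` (cm) from the
#' source centre and polar angle `theta` (radians in \[0, pi\]) measured from
#' the source long axis. Produced by [yzToPolar()] from bench coordinates.
#'
#' @slot r numeric, radial distances (cm), all positive.
#' @slot theta numeric, polar angles (radians in \[0, pi\]).
#' @export
setClass("PolarPoint", slots = c(r = "numeric", theta = "numeric"))

setValidity("PolarPoint", function(object) {
  msg <- character()
  if (length(object@r) != length(object@theta))
    msg <- c(msg, "r and theta must have the same length")
  if (any(object@r <= 0)) msg <- c(msg, "all radii must be positive")
  if (any(object@theta < 0 | object@theta > pi))
    msg <- c(msg, "theta must lie in [0, pi] radians")
  if (length(msg)) msg else TRUE
})

#' @param r radial distance(s), cm.
#' @param theta polar angle(s), radians in \[0, pi\].
#' @return A [PolarPoint-class] object.
#' @rdname PolarPoint-class
#' @export
polarPoint <- function(r, theta) new("PolarPoint", r = as.numeric(r),
                                     theta = as.numeric(theta))

#' SiPM datasheet parameters
#'
#' Device characteristics of a silicon photomultiplier that drive the
#' counting-mode simulation and the minimum-detectable-rate prediction.
#'
#' @slot name device model name.
#' @slot pde620 photon detection efficiency at 620 nm (fraction).
#' @slot dcr dark count rate at the 0.5 p.e. threshold, Hz.
#' @slot octProb optical cross-talk probability (fraction): probability that
#'   one primary avalanche fires at least one neighbouring cell, i.e. that
#'   the pulse exceeds the 1.5 p.e. level.
#' @slot sensitiveArea sensitive area, mm^2.
#' @slot cellPitch microcell pitch, micrometres.
#' @seealso [sipmSpec()], [sipmCatalog()]
#' @export
setClass("SiPMSpec",
  slots = c(name = "character", pde620 = "numeric", dcr = "numeric",
            octProb = "numeric", sensitiveArea = "numeric",
            cellPitch = "numeric"))

setValidity("SiPMSpec", function(object) {
  msg <- character()
  if (object@pde620 < 0 || object@pde620 > 1)
    msg <- c(msg, "pde620 must be a fraction in [0, 1]")
  if (object@dcr < 0) msg <- c(msg, "dcr must be >= 0")
  if (object@octProb < 0 || object@octProb >= 1)
    msg <- c(msg, "octProb must lie in [0, 1)")
  if (object@sensitiveArea <= 0) msg <- c(msg, "sensitiveArea must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SiPM specification
#'
#' @param name device model name.
#' @param pde620 photon detection efficiency at 620 nm (fraction).
#' @param dcr dark count rate at 0.5 p.e., Hz.
#' @param octProb optical cross-talk probability (fraction).
#' @param sensitiveArea sensitive area, mm^2.
#' @param cellPitch cell pitch, micrometres.
#' @return A [SiPMSpec-class] object.
#' @examples
#' pm1125 <- sipmCatalog()[["PM1125"]]
#' @export
sipmSpec <- function(name, pde620, dcr, octProb, sensitiveArea,
                     cellPitch = NA_real_) {
  new("SiPMSpec", name = name, pde620 = pde620, dcr = dcr, octProb = octProb,
      sensitiveArea = sensitiveArea, cellPitch = cellPitch)
}

#' Counting-run configuration
#'
#' Parameters of a counting-mode acquisition: the discriminator dead time
#' and its model, the counting window, the photo-electron threshold and the
#' number of repeated windows.
#'
#' @slot deadTime discriminator pulse duration \eqn{\tau} in seconds
#'   (default 35 ns, the shaped analog pulse width).
#' @slot deadTimeModel `"paralyzable"` (default; overlapping analog pulses
#'   extend the occupancy) or `"non-paralyzable"`.
#' @slot window counting window \eqn{\Delta t} in seconds.
#' @slot threshold discriminator threshold, 0.5 or 1.5 photo-electrons.
#' @slot nRepeats number of repeated counting windows per configuration.
#' @slot seed RNG seed recorded with simulated output (NA = do not reseed).
#' @seealso [simConfig()], [simulateCounts()]
#' @export
setClass("SimConfig",
  slots = c(deadTime = "numeric", deadTimeModel = "character",
            window = "numeric", threshold = "numeric", nRepeats = "integer",
            seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@deadTime < 0) msg <- c(msg, "deadTime must be >= 0")
  if (!object@deadTimeModel %in% c("paralyzable", "non-paralyzable"))
    msg <- c(msg, "deadTimeModel must be \"paralyzable\" or \"non-paralyzable\"")
  if (object@window <= 0) msg <- c(msg, "window must be > 0")
  if (!object@threshold %in% c(0.5, 1.5))
    msg <- c(msg, "threshold must be 0.5 or 1.5 p.e.")
  if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a counting-run configuration
#'
#' @param window counting window \eqn{\Delta t}, s.
#' @param deadTime dead time \eqn{\tau}, s (default 35e-9).
#' @param deadTimeModel `"paralyzable"` or `"non-paralyzable"`.
#' @param threshold 0.5 or 1.5 (photo-electrons).
#' @param nRepeats repeated windows (default 1).
#' @param seed optional integer RNG seed.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(window = 0.1, deadTime = 35e-9,
                      deadTimeModel = c("paralyzable", "non-paralyzable"),
                      threshold = 0.5, nRepeats = 1L, seed = NA_integer_) {
  new("SimConfig", deadTime = deadTime,
      deadTimeModel = match.arg(deadTimeModel), window = window,
      threshold = threshold, nRepeats = as.integer(nRepeats),
      seed = as.integer(seed))
}

#' Laboratory current scan
#'
#' An X-ray tube current scan: gross counts at each tube current with a
#' paired dark-count run taken after the irradiation (the per-point
#' dark-rate reference subtracted to obtain the photon counting rate, PCR).
#'
#' @slot data data.frame with columns `current_mA`, `gross_counts`,
#'   `dark_counts`, `window_s`; currents strictly increasing.
#' @slot threshold discriminator threshold label (0.5 or 1.5 p.e.).
#' @slot detector detector name.
#' @seealso [currentScan()], [subtractDCR()], [fitLinearity()]
#' @export
setClass("CurrentScan",
  slots = c(data = "data.frame", threshold = "numeric",
            detector = "character"))

.CURRENT_SCAN_COLS <- c("current_mA", "gross_counts", "dark_counts", "window_s")

setValidity("CurrentScan", function(object) {
  msg <- character()
  d <- object@data
  if (!all(.CURRENT_SCAN_COLS %in% names(d)))
    msg <- c(msg, paste("data must contain columns",
                        paste(.CURRENT_SCAN_COLS, collapse = ", ")))
  else {
    if (any(diff(d$current_mA) <= 0))
      msg <- c(msg, "currents must be strictly increasing")
    if (any(d$gross_counts < 0) || any(d$dark_counts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(d$window_s <= 0)) msg <- c(msg, "windows must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a laboratory current scan
#'
#' @param data data.frame with columns `current_mA`, `gross_counts`,
#'   `dark_counts`, `window_s`.
#' @param threshold threshold label, 0.5 or 1.5 p.e.
#' @param detector detector name.
#' @return A [CurrentScan-class] object.
#' @export
currentScan <- function(data, threshold = 0.5, detector = "unknown") {
  new("CurrentScan", data = as.data.frame(data), threshold = threshold,
      detector = detector)
}

#' Pre-clinical counting-rate scan
#'
#' Background-subtracted photon counting rates (PCR) recorded at a set of
#' sensor-source geometries, either bench coordinates `(y, z)` or polar
#' `(r, theta)`. Bench rows are converted with [yzToPolar()] at
#' construction, so every series carries canonical `r_cm` / `theta_rad`
#' columns.
#'
#' @slot data data.frame with columns `r_cm`, `theta_rad`, `pcr_khz`,
#'   `sigma_khz`, `window_s`, and optionally the original `y_cm`, `z_cm`.
#' @slot threshold threshold label (0.5 or 1.5 p.e.).
#' @slot detector detector name.
#' @slot sourceName label of the irradiating source.
#' @seealso [scanSeries()], [simulateSourceScan()], [symmetrisePCR()]
#' @export
setClass("ScanSeries",
  slots = c(data = "data.frame", threshold = "numeric",
            detector = "character", sourceName = "character"))

.SCAN_SERIES_COLS <- c("r_cm", "theta_rad", "pcr_khz", "sigma_khz", "window_s")

setValidity("ScanSeries", function(object) {
  msg <- character()
  d <- object@data
  if (!all(.SCAN_SERIES_COLS %in% names(d)))
    msg <- c(msg, paste("data must contain columns",
                        paste(.SCAN_SERIES_COLS, collapse = ", ")))
  else {
    if (any(d$r_cm <= 0)) msg <- c(msg, "all radii must be positive")
    if (any(d$theta_rad < 0 | d$theta_rad > pi))
      msg <- c(msg, "theta_rad must lie in [0, pi]")
    if (any(d$sigma_khz <= 0)) msg <- c(msg, "PCR uncertainties must be positive")
    if (any(d$window_s <= 0)) msg <- c(msg, "windows must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a pre-clinical scan series
#'
#' @param data data.frame holding either polar columns (`r_cm`, `theta_rad`)
#'   or bench columns (`y_cm`, `z_cm`, converted assuming the sensor sits at
#'   z = 0), plus `pcr_khz`, `sigma_khz`, `window_s`.
#' @param threshold threshold label (0.5 or 1.5).
#' @param detector detector name.
#' @param sourceName source label.
#' @return A [ScanSeries-class] object.
#' @export
scanSeries <- function(data, threshold = 1.5, detector = "unknown",
                       sourceName = "unknown") {
  data <- as.data.frame(data)
  if (!all(c("r_cm", "theta_rad") %in% names(data))) {
    if (!all(c("y_cm", "z_cm") %in% names(data)))
      stop("data must carry either (r_cm, theta_rad) or (y_cm, z_cm) columns")
    p <- yzToPolar(data$y_cm, data$z_cm, 0)
    data$r_cm <- p@r
    data$theta_rad <- p@theta
  }
  new("ScanSeries", data = data, threshold = threshold, detector = detector,
      sourceName = sourceName)
}

#' Weighted linear-fit summary of a current scan
#'
#' Result of the prefix-gated weighted least-squares linearity fit: the
#' sensitivity slope and intercept with uncertainties, the set of currents
#' retained (always a prefix of the scan, ordered by increasing current),
#' the reduced chi-squared of the retained set, and the upper linearity
#' limit (last retained current and its PCR).
#'
#' @slot slope,slopeSE sensitivity m and its uncertainty, kHz/mA.
#' @slot intercept,interceptSE intercept and uncertainty, kHz.
#' @slot included logical mask over scan rows (a prefix).
#' @slot chi2Reduced reduced chi-squared of the retained prefix.
#' @slot upperLimitCurrent last retained current, mA.
#' @slot upperLimitPcr PCR at the last retained current, kHz.
#' @seealso [fitLinearity()]
#' @export
setClass("LinearityFit",
  slots = c(slope = "numeric", slopeSE = "numeric", intercept = "numeric",
            interceptSE = "numeric", included = "logical",
            chi2Reduced = "numeric", upperLimitCurrent = "numeric",
            upperLimitPcr = "numeric"))

#' Laboratory figures of merit for one detector
#'
#' @slot detector detector name.
#' @slot dcrEstimate mean dark rate measured from the scan's dark runs, kHz.
#' @slot mdrMeasured minimum detectable rate per counting window (kHz),
#'   named by window length in seconds, computed from the measured dark rate.
#' @slot mdrDatasheet same, computed from the datasheet DCR (NA when no
#'   datasheet spec was supplied).
#' @slot sensitivity,sensitivitySE sensitivity m with uncertainty, kHz/mA.
#' @slot linearity the [LinearityFit-class].
#' @seealso [figuresOfMerit()]
#' @export
setClass("DetectorFigures",
  slots = c(detector = "character", dcrEstimate = "numeric",
            mdrMeasured = "numeric", mdrDatasheet = "numeric",
            sensitivity = "numeric", sensitivitySE = "numeric",
            linearity = "LinearityFit"))

#' Radial counting-rate profile fit
#'
#' Weighted nonlinear least-squares fit of the symmetrised counting-rate
#' profile to \eqn{h(r) = (a/r^2 + b/r + c)\,e^{-d r}} — an inverse-square
#' law near the source, attenuated exponentially at large distance.
#'
#' @slot coefficients named numeric `(a, b, c, d)`; `h` is in kHz with r in
#'   cm, so `a` is kHz cm^2, `b` kHz cm, `c` kHz and `d` 1/cm.
#' @slot covariance 4 x 4 parameter covariance matrix (unscaled, i.e. from
#'   the Poisson weights, not rescaled by the residual variance).
#' @slot chi2Reduced reduced chi-squared of the fit.
#' @slot domain fitted radial range `c(rMin, rMax)`, cm.
#' @seealso [fitH()], [hValue()], [hDerivative()]
#' @export
setClass("HFit",
  slots = c(coefficients = "numeric", covariance = "matrix",
            chi2Reduced = "numeric", domain = "numeric"))

setValidity("HFit", function(object) {
  msg <- character()
  if (length(object@coefficients) != 4L)
    msg <- c(msg, "coefficients must be the four parameters (a, b, c, d)")
  if (!all(dim(object@covariance) == c(4L, 4L)))
    msg <- c(msg, "covariance must be 4 x 4")
  if (length(object@domain) != 2L || object@domain[1] <= 0 ||
      diff(object@domain) <= 0)
    msg <- c(msg, "domain must be an increasing positive pair (rMin, rMax)")
  if (object@coefficients[["d"]] < 0)
    msg <- c(msg, "decay parameter d must be >= 0")
  if (length(msg)) msg else TRUE
})

#' System specification table
#'
#' Performance targets of the dosimetric system per treatment mode: maximum
#' sensing distance, spatial-resolution target at a stated distance,
#' statistical-precision target in a stated window at a stated distance.
#'
#' @slot specs data.frame with columns `mode`, `max_distance_cm`,
#'   `resolution_mm`, `resolution_at_cm`, `precision_frac`,
#'   `precision_window_s`, `precision_at_cm`.
#' @seealso [defaultSpecTable()], [complianceReport()]
#' @export
setClass("SpecTable", slots = c(specs = "data.frame"))

setValidity("SpecTable", function(object) {
  need <- c("mode", "max_distance_cm", "resolution_mm", "resolution_at_cm",
            "precision_frac", "precision_window_s", "precision_at_cm")
  if (!all(need %in% names(object@specs)))
    return(paste("specs must contain columns", paste(need, collapse = ", ")))
  num <- object@specs[setdiff(need, "mode")]
  if (any(unlist(num) <= 0)) return("all specification entries must be positive")
  TRUE
})

#' Performance report against the system specification
#'
#' @slot mode `"HDR"` or `"LDR"`.
#' @slot checks data.frame with one row per criterion: measured `value`, its
#'   `sigma`, the `target`, the comparison direction and the `pass` flag.
#' @slot mdrCrossing,mdrCrossingSE distance (cm) at which the fitted profile
#'   falls to the minimum detectable rate, with uncertainty (NA when the
#'   crossing lies beyond the fitted domain).
#' @seealso [complianceReport()]
#' @export
setClass("PerformanceReport",
  slots = c(mode = "character", checks = "data.frame",
            mdrCrossing = "numeric", mdrCrossingSE = "numeric"))
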