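# Accessors and show() methods.

#' Scan data accessor
#'
#' @param object a [CurrentScan-class] or [ScanSeries-class].
#' @return The underlying data.frame.
#' @export
setGeneric("scanData", function(object) standardGeneric("scanData"))

#' @rdname scanData
#' @export
setMethod("scanData", "CurrentScan", function(object) object@data)

#' @rdname scanData
#' @export
setMethod("scanData", "ScanSeries", function(object) object@data)

#' Detector-name accessor
#'
#' @param object a scan or figures object.
#' @return Character detector name.
#' @export
setGeneric("detectorName", function(object) standardGeneric("detectorName"))

#' @rdname detectorName
#' @export
setMethod("detectorName", "CurrentScan", function(object) object@detector)

#' @rdname detectorName
#' @export
setMethod("detectorName", "ScanSeries", function(object) object@detector)

#' @rdname detectorName
#' @export
setMethod("detectorName", "DetectorFigures", function(object) object@detector)

#' Threshold label accessor
#'
#' @param object a scan object.
#' @return Numeric threshold in photo-electrons (0.5 or 1.5).
#' @export
setGeneric("thresholdLabel", function(object) standardGeneric("thresholdLabel"))

#' @rdname thresholdLabel
#' @export
setMethod("thresholdLabel", "CurrentScan", function(object) object@threshold)

#' @rdname thresholdLabel
#' @export
setMethod("thresholdLabel", "ScanSeries", function(object) object@threshold)

#' @describeIn HFit-class fitted parameters `(a, b, c, d)`.
#' @param object an [HFit-class] or [LinearityFit-class].
#' @export
setMethod("coef", "HFit", function(object) object@coefficients)

#' @describeIn HFit-class parameter covariance matrix.
#' @export
setMethod("vcov", "HFit", function(object) object@covariance)

#' @describeIn LinearityFit-class `(intercept, slope)` in kHz and kHz/mA.
#' @param object a [LinearityFit-class].
#' @export
setMethod("coef", "LinearityFit", function(object)
  c(intercept = object@intercept, slope = object@slope))

setMethod("show", "SiPMSpec", function(object) {
  cat(sprintf("SiPM '%s': PDE(620 nm) %.0f%%, DCR %.0f kHz, OCT %.0f%%, area %.2f mm^2\n",
              object@name, 100 * object@pde620, object@dcr / 1e3,
              100 * object@octProb, object@sensitiveArea))
})

setMethod("show", "SourceSpec", function(object) {
  aniso <- if (is.character(object@anisotropy)) "point source"
  else sprintf("%d x %d anisotropy table", length(object@anisotropy@rGrid),
               length(object@anisotropy@thetaGrid))
  cat(sprintf("TG-43 source: s_k = %g, Lambda = %g, L = %g cm, %s, reference (%g cm, %.0f deg)\n",
              object@airKermaStrength, object@doseRateConstant,
              object@capsuleLength, aniso, object@r0,
              object@theta0 * 180 / pi))
})

setMethod("show", "AnisotropyTable", function(object) {
  cat(sprintf("Anisotropy table: r in [%g, %g] cm (%d), theta in [%g, %g] deg (%d)\n",
              min(object@rGrid), max(object@rGrid), length(object@rGrid),
              min(object@thetaGrid), max(object@thetaGrid),
              length(object@thetaGrid)))
})

setMethod("show", "CurrentScan", function(object) {
  cat(sprintf("Current scan, detector '%s' at %.1f p.e.: %d points, %g-%g mA\n",
              object@detector, object@threshold, nrow(object@data),
              min(object@data$current_mA), max(object@data$current_mA)))
})

setMethod("show", "ScanSeries", function(object) {
  cat(sprintf("Scan series, detector '%s' at %.1f p.e., source '%s': %d points, r in [%.2f, %.2f] cm\n",
              object@detector, object@threshold, object@sourceName,
              nrow(object@data), min(object@data$r_cm),
              max(object@data$r_cm)))
})

setMethod("show", "LinearityFit", function(object) {
  cat(sprintf("Linearity fit: m = %.0f +/- %.0f kHz/mA, intercept %.1f +/- %.1f kHz\n",
              object@slope, object@slopeSE, object@intercept,
              object@interceptSE))
  cat(sprintf("  %d/%d points retained (chi2/dof = %.2f), upper limit %.2f mA / %.0f kHz\n",
              sum(object@included), length(object@included),
              object@chi2Reduced, object@upperLimitCurrent,
              object@upperLimitPcr))
})

setMethod("show", "DetectorFigures", function(object) {
  cat(sprintf("Detector '%s': measured DCR %.1f kHz\n", object@detector,
              object@dcrEstimate))
  for (w in names(object@mdrMeasured))
    cat(sprintf("  MDR(%s s) = %.2f kHz (datasheet: %s kHz)\n", w,
                object@mdrMeasured[[w]],
                ifelse(is.na(object@mdrDatasheet[[w]]), "-",
                       sprintf("%.2f", object@mdrDatasheet[[w]]))))
  cat(sprintf("  sensitivity m = %.0f +/- %.0f kHz/mA\n", object@sensitivity,
              object@sensitivitySE))
})

setMethod("show", "HFit", function(object) {
  cf <- object@coefficients
  cat(sprintf("Radial profile h(r) = (a/r^2 + b/r + c) exp(-d r) on [%.2f, %.2f] cm\n",
              object@domain[1], object@domain[2]))
  cat(sprintf("  a = %.4g kHz cm^2, b = %.4g kHz cm, c = %.4g kHz, d = %.4g /cm, chi2/dof = %.2f\n",
              cf[["a"]], cf[["b"]], cf[["c"]], cf[["d"]],
              object@chi2Reduced))
})

setMethod("show", "PerformanceReport", function(object) {
  cat(sprintf("Performance report (%s mode):\n", object@mode))
  ck <- object@checks
  for (i in seq_len(nrow(ck)))
    cat(sprintf("  %-28s %.4g %s %.4g at %g cm: %s\n", ck$criterion[i],
                ck$value[i], ck$direction[i], ck$target[i], ck$at_cm[i],
                ifelse(ck$pass[i], "PASS", "FAIL")))
  if (!is.na(object@mdrCrossing))
    cat(sprintf("  profile crosses the MDR at %.2f +/- %.2f cm\n",
                object@mdrCrossing, object@mdrCrossingSE))
})
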