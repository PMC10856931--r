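# Laboratory figures of merit: per-point dark-rate subtraction, minimum
# detectable rate, chi-bar^2-gated linearity range and sensitivity.

#' Datasheet catalog of the candidate SiPMs
#'
#' The four devices compared during the laboratory characterisation — two
#' 25 um pitch KETEK devices and two HAMAMATSU MPPCs — with their datasheet
#' photon detection efficiency at 620 nm, dark count rate at the 0.5 p.e.
#' threshold, optical cross-talk probability, sensitive area and cell pitch.
#'
#' @return Named list of [SiPMSpec-class] objects:
#'   `PM1125`, `PM3325`, `S13360-1350`, `S13360-1375`.
#' @examples
#' sipmCatalog()[["S13360-1375"]]@dcr  # 90 kHz in Hz
#' @export
sipmCatalog <- function() {
  list(
    "PM1125" = sipmSpec("PM1125", pde620 = 0.17, dcr = 125e3,
                        octProb = 0.26, sensitiveArea = 1.0, cellPitch = 25),
    "PM3325" = sipmSpec("PM3325", pde620 = 0.17, dcr = 1125e3,
                        octProb = 0.26, sensitiveArea = 9.0, cellPitch = 25),
    "S13360-1350" = sipmSpec("S13360-1350", pde620 = 0.24, dcr = 90e3,
                             octProb = 0.03, sensitiveArea = 1.69,
                             cellPitch = 50),
    "S13360-1375" = sipmSpec("S13360-1375", pde620 = 0.30, dcr = 90e3,
                             octProb = 0.07, sensitiveArea = 1.69,
                             cellPitch = 75))
}

#' Measured laboratory benchmark figures
#'
#' The reference laboratory characterisation of the four candidate devices:
#' minimum detectable rate in the 0.1 s and 0.5 s windows, linearity upper
#' limit and sensitivity, at both discriminator thresholds. These measured
#' figures serve as comparison inputs for consistency checks (e.g. the
#' sqrt(window) MDR scaling, or sensitivity ratios against datasheet PDE
#' ratios).
#'
#' @return data.frame with columns `detector`, `threshold_pe`,
#'   `mdr_0.1s_khz`, `mdr_0.1s_err`, `mdr_0.5s_khz`, `mdr_0.5s_err`,
#'   `sensitivity_khz_mA`, `sensitivity_err`, `upper_limit_mA`,
#'   `upper_limit_mhz` (total-rate upper limit, NA at 1.5 p.e. where the
#'   full current range stayed linear).
#' @export
benchmarkFigures <- function() {
  data.frame(
    detector = rep(c("PM1125", "PM3325", "S13360-1350", "S13360-1375"), 2),
    threshold_pe = rep(c(0.5, 1.5), each = 4),
    mdr_0.1s_khz = c(3.1, 10.5, 3.0, 2.8, 1.5, 5.5, 0.49, 0.47),
    mdr_0.1s_err = c(0.2, 0.3, 0.2, 0.2, 0.1, 0.2, 0.07, 0.07),
    mdr_0.5s_khz = c(1.4, 4.7, 1.4, 1.2, 0.68, 2.5, 0.22, 0.21),
    mdr_0.5s_err = c(0.05, 0.1, 0.05, 0.05, 0.04, 0.07, 0.002, 0.002),
    sensitivity_khz_mA = c(6710, 12438, 14203, 18187, 1713, 3192, 354, 533),
    sensitivity_err = c(31, 448, 354, 378, 22, 31, 3, 4),
    upper_limit_mA = c(0.6, 0.25, 0.3, 0.25, 1, 1, 1, 1),
    upper_limit_mhz = c(4.04, 3.09, 4.31, 4.43, NA, NA, NA, NA))
}

#' Per-point dark-rate subtraction
#'
#' Converts a current scan to photon counting rates: each point's dark run,
#' taken right after the irradiation (so that slow afterglow contributes to
#' both), is subtracted, \eqn{PCR_i = (N_{gross,i} - N_{dark,i})/\Delta t},
#' with the Poisson uncertainty
#' \eqn{\sigma_i = \sqrt{N_{gross,i} + N_{dark,i}}/\Delta t}. Negative PCR
#' values (downward fluctuations of a null signal) are kept and flagged.
#'
#' @param scan a [CurrentScan-class].
#' @return data.frame with columns `current_mA`, `pcr_khz`, `sigma_khz`,
#'   `negative` (logical flag).
#' @examples
#' d <- data.frame(current_mA = 0.1, gross_counts = 10000L,
#'                 dark_counts = 2500L, window_s = 0.1)
#' subtractDCR(currentScan(d))  # PCR = 75 kHz, sigma = 1.118 kHz
#' @export
subtractDCR <- function(scan) {
  d <- scan@data
  pcr <- (d$gross_counts - d$dark_counts) / d$window_s / 1e3
  sig <- sqrt(d$gross_counts + d$dark_counts) / d$window_s / 1e3
  sig[sig <= 0] <- 1 / d$window_s[sig <= 0] / 1e3   # zero-count floor
  data.frame(current_mA = d$current_mA, pcr_khz = pcr, sigma_khz = sig,
             negative = pcr < 0)
}

#' Minimum detectable rate
#'
#' The counting rate whose expected counts equal three times the Poisson
#' fluctuation of the dark counts in the window:
#' \eqn{MDR \cdot \Delta t = 3\sqrt{DCR \cdot \Delta t}}, i.e.
#' \eqn{MDR = 3\sqrt{DCR/\Delta t}}. Longer windows lower the MDR as
#' \eqn{1/\sqrt{\Delta t}}.
#'
#' @param dcr dark count rate(s), Hz.
#' @param window counting window \eqn{\Delta t}, s.
#' @return Minimum detectable rate(s), Hz.
#' @examples
#' mdr(90e3, 0.1) / 1e3  # 2.846 kHz
#' @export
mdr <- function(dcr, window) {
  if (any(dcr < 0)) stop("dcr must be non-negative")
  if (any(window <= 0)) stop("window must be positive")
  3 * sqrt(dcr / window)
}

# weighted least squares of pcr ~ current with fixed Poisson weights;
# covariance is the pure weight-matrix one, not rescaled by the dispersion
.wlsLine <- function(x, y, sigma) {
  w <- 1 / sigma^2
  fit <- stats::lm(y ~ x, weights = w)
  chi2 <- sum(w * stats::residuals(fit)^2)
  # covariance from the fixed Poisson weights, (X' W X)^-1, not rescaled by
  # the residual dispersion
  X <- cbind(1, x)
  vc <- solve(crossprod(X, w * X))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       interceptSE = sqrt(vc[1, 1]), slopeSE = sqrt(vc[2, 2]),
       chi2 = chi2)
}

#' Prefix-gated linearity fit
#'
#' Weighted least squares of PCR on tube current with Poisson weights
#' \eqn{1/\sigma_i^2}. Points are added in order of increasing current and
#' the retained set is the largest prefix whose reduced chi-squared
#' \eqn{\bar\chi^2 = \chi^2 / (n - 2)} stays at or below `chi2Max`
#' (default 2.7, roughly the 90% confidence level at one residual degree of
#' freedom). Only the highest currents are ever excluded — pile-up bends
#' the response down from above, never in the interior.
#'
#' @param pcrSeries data.frame with columns `current_mA`, `pcr_khz`,
#'   `sigma_khz` (e.g. from [subtractDCR()]), or a [CurrentScan-class].
#' @param chi2Max reduced chi-squared gate (default 2.7).
#' @return A [LinearityFit-class]; errors when fewer than 3 points are
#'   supplied or no 3-point prefix passes the gate.
#' @export
fitLinearity <- function(pcrSeries, chi2Max = 2.7) {
  if (is(pcrSeries, "CurrentScan")) pcrSeries <- subtractDCR(pcrSeries)
  n <- nrow(pcrSeries)
  if (n < 3L) stop("insufficient data: at least 3 scan points are required")
  best <- NULL
  for (k in 3:n) {
    f <- .wlsLine(pcrSeries$current_mA[1:k], pcrSeries$pcr_khz[1:k],
                  pcrSeries$sigma_khz[1:k])
    if (f$chi2 / (k - 2) <= chi2Max) best <- c(f, k = k)
  }
  if (is.null(best))
    stop("no linear range: every prefix exceeds the reduced chi-squared gate")
  k <- best$k
  new("LinearityFit", slope = best$slope, slopeSE = best$slopeSE,
      intercept = best$intercept, interceptSE = best$interceptSE,
      included = seq_len(n) <= k, chi2Reduced = best$chi2 / (k - 2),
      upperLimitCurrent = pcrSeries$current_mA[k],
      upperLimitPcr = pcrSeries$pcr_khz[k])
}

#' Assemble the laboratory figures of merit
#'
#' Computes, from one current scan: the mean dark rate over the scan's
#' paired dark runs; the minimum detectable rate in each requested window
#' from that measured dark rate (and, when a datasheet spec is supplied,
#' from the datasheet DCR for comparison); and the sensitivity with its
#' linearity limits from the prefix-gated fit.
#'
#' @param scan a [CurrentScan-class].
#' @param spec optional [SiPMSpec-class] for the datasheet-DCR comparison.
#' @param windows counting windows in seconds (default `c(0.1, 0.5)`, the
#'   high- and low-dose-rate windows).
#' @param chi2Max reduced chi-squared gate for [fitLinearity()].
#' @return A [DetectorFigures-class].
#' @export
figuresOfMerit <- function(scan, spec = NULL, windows = c(0.1, 0.5),
                           chi2Max = 2.7) {
  d <- scan@data
  dcrHat <- mean(d$dark_counts / d$window_s)   # Hz
  mdrMeas <- mdr(dcrHat, windows) / 1e3
  names(mdrMeas) <- as.character(windows)
  if (!is.null(spec)) {
    dcrSheet <- applyThreshold(spec@dcr, spec, scan@threshold)
    mdrSheet <- mdr(dcrSheet, windows) / 1e3
  } else mdrSheet <- rep(NA_real_, length(windows))
  names(mdrSheet) <- as.character(windows)
  lin <- fitLinearity(subtractDCR(scan), chi2Max = chi2Max)
  new("DetectorFigures", detector = scan@detector, dcrEstimate = dcrHat / 1e3,
      mdrMeasured = mdrMeas, mdrDatasheet = mdrSheet,
      sensitivity = lin@slope, sensitivitySE = lin@slopeSE, linearity = lin)
}
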