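# Counting-mode SiPM measurement simulator: Poisson photon and dark counts,
# optical cross-talk thinning at the 1.5 p.e. threshold, and analytic
# dead-time (pile-up) distortion of the true rate.

#' Pile-up probability
#'
#' Probability that a pulse overlaps its predecessor within the dead time
#' \eqn{\tau}: for Poisson arrivals at rate R the preceding gap is shorter
#' than \eqn{\tau} with probability \eqn{1 - e^{-R\tau}}.
#'
#' @param rate true pulse rate, Hz.
#' @param tau dead time (discriminator pulse duration), s.
#' @return Pile-up fraction(s) in \[0, 1).
#' @examples
#' pileupProbability(4e6, 35e-9)  # ~0.13: above 10% at 4 MHz
#' @export
pileupProbability <- function(rate, tau) {
  if (any(rate < 0) || any(tau < 0))
    stop("rate and tau must be non-negative")
  1 - exp(-rate * tau)
}

#' Observed counting rate under dead time
#'
#' Analytic dead-time response mapping the true pulse rate R to the rate a
#' counter registers: paralyzable \eqn{R e^{-R\tau}} (each pulse extends the
#' busy period, the model matching overlapping shaped analog pulses) or
#' non-paralyzable \eqn{R / (1 + R\tau)}. Both are monotone sub-linear.
#'
#' @param trueRate true pulse rate(s), Hz.
#' @param cfg a [SimConfig-class] (uses `deadTime` and `deadTimeModel`), or
#'   a numeric dead time in seconds.
#' @param model dead-time model when `cfg` is numeric.
#' @return Registered rate(s), Hz.
#' @examples
#' observedRate(4e6, simConfig(deadTime = 35e-9))  # 4e6 * exp(-0.14)
#' @export
observedRate <- function(trueRate,
                         cfg = simConfig(),
                         model = c("paralyzable", "non-paralyzable")) {
  if (any(trueRate < 0)) stop("trueRate must be non-negative")
  if (is(cfg, "SimConfig")) { tau <- cfg@deadTime; model <- cfg@deadTimeModel }
  else { tau <- cfg; model <- match.arg(model) }
  if (tau < 0) stop("dead time must be non-negative")
  switch(model,
         paralyzable = trueRate * exp(-trueRate * tau),
         `non-paralyzable` = trueRate / (1 + trueRate * tau))
}

#' Rate passing the discriminator threshold
#'
#' At the 0.5 p.e. threshold every primary avalanche is counted. At the
#' 1.5 p.e. threshold a primary avalanche is counted only when it fires at
#' least one neighbouring cell through optical cross-talk — by the
#' datasheet definition of the cross-talk probability this is Bernoulli
#' thinning with probability `octProb`.
#'
#' @param primaryRate primary avalanche rate(s), Hz.
#' @param spec a [SiPMSpec-class].
#' @param threshold 0.5 or 1.5 (photo-electrons).
#' @return Mean rate(s) above threshold, Hz.
#' @export
applyThreshold <- function(primaryRate, spec, threshold) {
  if (any(primaryRate < 0)) stop("primaryRate must be non-negative")
  if (identical(threshold, 0.5)) return(primaryRate)
  if (identical(threshold, 1.5)) return(spec@octProb * primaryRate)
  stop("configuration error: threshold must be 0.5 or 1.5 p.e.")
}

# core sampler, never reseeds: gross and paired dark windows
.sampleCounts <- function(trueRate, dcr, cfg) {
  grossRate <- observedRate(trueRate + dcr, cfg)
  darkRate <- observedRate(dcr, cfg)
  n <- cfg@nRepeats
  data.frame(gross_counts = stats::rpois(n, grossRate * cfg@window),
             dark_counts = stats::rpois(n, darkRate * cfg@window),
             window_s = cfg@window, threshold = cfg@threshold)
}

#' Simulate one counting measurement
#'
#' Draws gross counts from Poisson(`observedRate(trueRate + dcr) * window`)
#' and, from an independent paired run, dark counts from
#' Poisson(`observedRate(dcr) * window`). One row per repeat.
#'
#' @param trueRate true signal pulse rate above threshold, Hz.
#' @param dcr dark pulse rate above threshold, Hz.
#' @param cfg a [SimConfig-class]; its `seed`, when not NA, reseeds the RNG
#'   so the measurement is reproducible.
#' @return data.frame with columns `gross_counts`, `dark_counts`,
#'   `window_s`, `threshold`.
#' @export
simulateCounts <- function(trueRate, dcr, cfg = simConfig()) {
  if (trueRate < 0 || dcr < 0) stop("rates must be non-negative")
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  .sampleCounts(trueRate, dcr, cfg)
}

#' Default X-ray tube current grid
#'
#' The laboratory scan grid: 0.05 mA steps from 0.05 to 0.3 mA, then 0.1 mA
#' steps up to 1.0 mA (13 points).
#'
#' @return Numeric vector of currents, mA.
#' @export
defaultCurrentGrid <- function() c(seq(0.05, 0.30, by = 0.05),
                                   seq(0.40, 1.00, by = 0.10))

#' Simulate a laboratory current scan
#'
#' Emulates the X-ray characterisation protocol: at each tube current I the
#' true primary photon rate is `sensitivityTrue * I` (kHz/mA times mA);
#' photon and dark rates are thinned by the discriminator threshold,
#' distorted by dead time, and Poisson-sampled, with a paired dark run per
#' point.
#'
#' @param sensitivityTrue true sensitivity at the 0.5 p.e. threshold,
#'   kHz/mA.
#' @param spec a [SiPMSpec-class] (supplies the dark rate and the
#'   cross-talk probability).
#' @param cfg a [SimConfig-class]; `threshold` selects 0.5 or 1.5 p.e. The
#'   default 1 ms gate matches a frequency-counter acquisition whose
#'   point-to-point spread reproduces the bench behaviour (dead-time
#'   curvature emerging from the noise in the few-MHz region).
#' @param currents tube currents in mA, positive and increasing.
#' @return A [CurrentScan-class].
#' @examples
#' spec <- sipmCatalog()[["PM1125"]]
#' scan <- simulateCurrentScan(18000, spec, simConfig(window = 1e-3, seed = 1L))
#' @export
simulateCurrentScan <- function(sensitivityTrue, spec,
                                cfg = simConfig(window = 1e-3),
                                currents = defaultCurrentGrid()) {
  if (any(currents <= 0) || any(diff(currents) <= 0))
    stop("currents must be positive and strictly increasing")
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  photon <- applyThreshold(sensitivityTrue * 1e3 * currents, spec,
                           cfg@threshold)
  dark <- applyThreshold(spec@dcr, spec, cfg@threshold)
  rows <- do.call(rbind, lapply(seq_along(currents), function(i) {
    one <- cfg; one@nRepeats <- 1L
    cbind(current_mA = currents[i], .sampleCounts(photon[i], dark, one))
  }))
  currentScan(rows[c("current_mA", "gross_counts", "dark_counts", "window_s")],
              threshold = cfg@threshold, detector = spec@name)
}

#' Pre-clinical measurement grids
#'
#' The phantom geometries of the pre-clinical campaigns. `hdrGeometryGrid()`
#' is the bench grid of the high-dose-rate study: the sensor at transverse
#' distances y of 0.5, 1, 2, 3 and 5 cm while the source travels along z —
#' in 2.5 mm increments throughout at y = 0.5 cm (|z| up to 2 cm), and for
#' the remaining y positions 2.5 mm increments for |z| < 2 cm widening to
#' 5 mm out to |z| = 5 cm. `ldrGeometryGrid()` is the low-dose-rate radial
#' grid: transverse-plane distances from 5 mm to 20 mm in 1 mm steps
#' (16 points).
#'
#' @param y transverse sensor distances, cm.
#' @param zReach outermost |z| for the wide-step section, cm.
#' @return data.frame of bench (`y_cm`, `z_cm`) or polar
#'   (`r_cm`, `theta_rad`) geometries.
#' @export
hdrGeometryGrid <- function(y = c(0.5, 1, 2, 3, 5), zReach = 5) {
  rows <- lapply(y, function(yy) {
    z <- if (yy < 1) seq(-2, 2, by = 0.25)
    else c(seq(-zReach, -2.5, by = 0.5), seq(-2, 2, by = 0.25),
           seq(2.5, zReach, by = 0.5))
    data.frame(y_cm = yy, z_cm = z)
  })
  do.call(rbind, rows)
}

#' @rdname hdrGeometryGrid
#' @export
ldrGeometryGrid <- function() {
  data.frame(r_cm = seq(0.5, 2.0, by = 0.1),
             theta_rad = pi / 2)
}

#' Simulate a pre-clinical source scan
#'
#' Uses the TG43-U1 dose rate as ground truth: at each geometry the primary
#' photon rate is `conversionK` times the model dose rate, optionally
#' contaminated by a z-asymmetric stem term, thinned by the threshold,
#' distorted by dead time and Poisson-sampled with a paired dark run. The
#' background-subtracted PCR and its Poisson uncertainty are returned.
#'
#' The optional stem term emulates, qualitatively only, spurious light
#' generated in the clear fibre: an additive primary rate
#' `stemCoef * max(-z, 0)` Hz, largest when the source sits at negative z
#' where the fibre faces the source. It is off (`stemCoef = 0`) by default.
#'
#' @param src a [SourceSpec-class].
#' @param geometry data.frame with bench columns `y_cm`, `z_cm` (sensor at
#'   z = 0) or polar columns `r_cm`, `theta_rad`.
#' @param conversionK conversion factor, Hz of primary avalanches per dose
#'   -rate unit.
#' @param spec a [SiPMSpec-class].
#' @param cfg a [SimConfig-class].
#' @param stemCoef stem-contamination coefficient, Hz/cm (default 0).
#' @return A [ScanSeries-class].
#' @export
simulateSourceScan <- function(src, geometry, conversionK, spec,
                               cfg = simConfig(), stemCoef = 0) {
  geometry <- as.data.frame(geometry)
  if (all(c("y_cm", "z_cm") %in% names(geometry))) {
    p <- yzToPolar(geometry$y_cm, geometry$z_cm, 0)
    geometry$r_cm <- p@r
    geometry$theta_rad <- p@theta
    zc <- geometry$z_cm
  } else if (all(c("r_cm", "theta_rad") %in% names(geometry))) {
    zc <- -geometry$r_cm * cos(geometry$theta_rad)  # implied source z offset
  } else stop("geometry needs (y_cm, z_cm) or (r_cm, theta_rad) columns")
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  d <- doseRate(polarPoint(geometry$r_cm, geometry$theta_rad), src)
  primary <- conversionK * d + stemCoef * pmax(-zc, 0)
  photon <- applyThreshold(primary, spec, cfg@threshold)
  dark <- applyThreshold(spec@dcr, spec, cfg@threshold)
  counts <- do.call(rbind, lapply(photon, function(rate) {
    one <- cfg; one@nRepeats <- 1L
    .sampleCounts(rate, dark, one)
  }))
  geometry$pcr_khz <- (counts$gross_counts - counts$dark_counts) /
    cfg@window / 1e3
  geometry$sigma_khz <- sqrt(counts$gross_counts + counts$dark_counts) /
    cfg@window / 1e3
  geometry$sigma_khz[geometry$sigma_khz <= 0] <- 1 / cfg@window / 1e3
  geometry$window_s <- cfg@window
  scanSeries(geometry, threshold = cfg@threshold, detector = spec@name,
             sourceName = "simulated")
}
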