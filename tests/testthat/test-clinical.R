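# Pre-clinical pipeline: calibration, energy correction, symmetrisation,
# radial profile fit, precision, resolution, MDR crossing and compliance.

test_that("reference-point calibration recovers the conversion factor", {
  ps <- sourceSpec(airKermaStrength = 1000, doseRateConstant = 1)
  spec <- sipmSpec("ideal", 0.2, dcr = 1e4, octProb = 0.2, sensitiveArea = 1)
  geom <- data.frame(r_cm = c(1, 1.5, 2, 3, 4), theta_rad = pi / 2)
  ser <- simulateSourceScan(ps, geom, conversionK = 3000, spec,
                            simConfig(window = 1, deadTime = 0, seed = 61L))
  cal <- calibrateAtReference(ser, ps)
  expect_lt(abs(cal$k - 3), 3 * cal$kSE)   # 3000 Hz -> 3 kHz per unit

  # identity: k = PCR(r0)/ (s_k Lambda)
  d <- scanData(ser)
  expect_equal(cal$k, d$pcr_khz[d$r_cm == 2] / 1000)

  # no point near the reference
  far <- scanSeries(data.frame(r_cm = c(1, 4), theta_rad = pi / 2,
                               pcr_khz = 1, sigma_khz = 0.1, window_s = 1))
  expect_error(calibrateAtReference(far, ps), "calibration error")

  # two equidistant candidates are ambiguous
  tie <- scanSeries(data.frame(r_cm = c(1.98, 2.02), theta_rad = pi / 2,
                               pcr_khz = 1, sigma_khz = 0.1, window_s = 1))
  expect_error(calibrateAtReference(tie, ps), "equidistant")
})

test_that("energy-correction ratios are unity for model-exact data", {
  src <- exampleHdrSource()
  ser <- exactSeries(src, hdrGeometryGrid(y = c(2, 3, 5)), k = 0.03)
  ec <- energyCorrectionCurve(ser, src, k = 0.03)
  expect_true(all(abs(ec$points$ratio - 1) < 1e-9))
  expect_lt(abs(ec$slope), 3 * ec$slopeSE + 1e-12)
})

test_that("an injected linear energy response is recovered by the ratio fit", {
  src <- exampleHdrSource()
  ser <- exactSeries(src, hdrGeometryGrid(y = c(2, 3, 5)), k = 0.03,
                     sigmaFrac = 2e-3)
  d <- scanData(ser)
  set.seed(71)
  drift <- 1 + 0.05 * (d$r_cm - src@r0)
  d$pcr_khz <- d$pcr_khz * drift + rnorm(nrow(d), 0, d$sigma_khz)
  serDrift <- scanSeries(d, threshold = 1.5)
  ec <- energyCorrectionCurve(serDrift, src, k = 0.03)
  expect_lt(abs(ec$slope - 0.05), 3 * ec$slopeSE)
})

test_that("LDR-mode ratios stay consistent with unity across distance", {
  src <- exampleLdrSource()
  spec <- sipmCatalog()[["S13360-1375"]]
  ser <- simulateSourceScan(src, ldrGeometryGrid(), conversionK = 35000, spec,
                            simConfig(window = 0.5, deadTime = 0, seed = 81L))
  cal <- calibrateAtReference(ser, src)
  ec <- energyCorrectionCurve(ser, src, cal$k)
  expect_lt(abs(ec$slope), 3 * ec$slopeSE)
  # each ratio consistent with 1 within its Poisson error plus the shared
  # calibration-scale uncertainty
  tot <- sqrt(ec$points$sigma^2 + (ec$points$ratio * cal$kSE / cal$k)^2)
  expect_true(all(abs(ec$points$ratio - 1) < 4 * tot))
})

test_that("symmetrisation is the identity on the transverse plane and scales by 1/F", {
  src <- exampleHdrSource(anisotropy = "point")
  ser <- scanSeries(data.frame(r_cm = 3, theta_rad = pi / 2, pcr_khz = 50,
                               sigma_khz = 1, window_s = 0.1))
  sym <- symmetrisePCR(ser, src)
  expect_equal(sym$pcr_khz, 50)

  # constant F = 2, G ratio = 1 (point-source geometry): PCR_Sym = PCR / 2
  tabF2 <- suppressWarnings(anisotropyTable(c(1, 5), c(0, 180),
                                            matrix(2, 2, 2)))
  srcF2 <- sourceSpec(1000, 1, capsuleLength = 0, anisotropy = tabF2)
  symF2 <- symmetrisePCR(ser, srcF2)
  expect_equal(symF2$pcr_khz, 25)
})

test_that("symmetrised rates from different angles collapse onto one radial profile", {
  src <- exampleHdrSource()
  spec <- sipmCatalog()[["PM1125"]]
  # several angles at (nearly) fixed r: bench points on a circle of r = 3
  th <- seq(0.6, pi - 0.6, length.out = 7)
  geom <- data.frame(r_cm = rep(3, 7), theta_rad = th)
  ser <- simulateSourceScan(src, geom, 120, spec,
                            simConfig(window = 0.5, deadTime = 0,
                                      threshold = 1.5, seed = 91L))
  sym <- symmetrisePCR(ser, src)
  # all pairs agree within 3 sigma of their combined uncertainty
  for (i in 1:6) for (j in (i + 1):7)
    expect_lt(abs(sym$pcr_khz[i] - sym$pcr_khz[j]),
              3 * sqrt(sym$sigma_khz[i]^2 + sym$sigma_khz[j]^2))

  # exact-model check: collapse is exact without noise
  serX <- exactSeries(src, geom, k = 0.03)
  symX <- symmetrisePCR(serX, src)
  expect_lt(diff(range(symX$pcr_khz)) / mean(symX$pcr_khz), 1e-9)
})

test_that("stem-affected rows can be excluded by transverse distance", {
  src <- exampleHdrSource()
  ser <- exactSeries(src, hdrGeometryGrid(), k = 0.03)
  sym <- symmetrisePCR(ser, src, yMin = 2)
  expect_true(all(sym$r_cm >= 2))
  expect_error(symmetrisePCR(scanSeries(
    data.frame(r_cm = 2, theta_rad = pi / 2, pcr_khz = 1, sigma_khz = 0.1,
               window_s = 1)), src, yMin = 2), "y_cm")
})

test_that("radial profile fit recovers known parameters from Poisson data", {
  # a far-field plateau well above the noise floor: with c buried in noise
  # the near-degenerate c-d direction makes linearised intervals optimistic
  truth <- c(a = 2500, b = 370, c = 30, d = 0.1)
  rr <- sort(unique(round(symmetrisePCR(
    exactSeries(exampleHdrSource(), hdrGeometryGrid(y = c(2, 3, 5)), 0.03),
    exampleHdrSource())$r_cm, 6)))
  hTrue <- (truth["a"] / rr^2 + truth["b"] / rr + truth["c"]) *
    exp(-truth["d"] * rr)
  window <- 0.1
  set.seed(103)
  counts <- rpois(length(rr), hTrue * 1e3 * window)
  radial <- data.frame(r_cm = rr, pcr_khz = counts / window / 1e3,
                       sigma_khz = sqrt(pmax(counts, 1)) / window / 1e3)
  fit <- fitH(radial)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  for (p in names(truth))
    expect_lt(abs(cf[[p]] - truth[[p]]), 3.5 * se[[p]],
              label = paste("parameter", p))
  expect_gt(fit@chi2Reduced, 0.4); expect_lt(fit@chi2Reduced, 1.8)
})

test_that("pure inverse-square data leave b, c, d compatible with zero", {
  rr <- seq(1, 8, by = 0.5)
  window <- 0.1
  set.seed(104)
  counts <- rpois(length(rr), 1e6 / rr^2 * window)
  radial <- data.frame(r_cm = rr, pcr_khz = counts / window / 1e3,
                       sigma_khz = sqrt(counts) / window / 1e3)
  fit <- fitH(radial)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(cf[["b"]]), 3 * se[["b"]])
  expect_lt(abs(cf[["c"]]), 3 * se[["c"]])
  expect_lt(cf[["d"]], 3 * se[["d"]])   # bounded below at 0
  expect_error(fitH(radial[1:4, ]), "at least 5")
})

test_that("statistical precision follows the combined-count formula", {
  # N_PCR = 1e4, no dark counts: SP = 1%
  fit <- makeHFit(a = 2500)   # h(5) = 100 kHz
  expect_equal(statisticalPrecision(5, 0.1, fit, 0)$value, 0.01)
  # N_PCR = 2700, N_DCR = 2500: SP = sqrt(5200)/2700
  fit27 <- makeHFit(a = 2700)   # h(10) = 27 kHz
  sp <- statisticalPrecision(10, 0.1, fit27, 25e3)
  expect_equal(sp$value, sqrt(2700 + 2500) / 2700, tolerance = 1e-12)
  expect_equal(round(100 * sp$value, 2), 2.67)
  # SP shrinks towards the source (h monotone decreasing)
  spSeq <- statisticalPrecision(c(2, 4, 6, 8), 0.1, fit27, 25e3)$value
  expect_true(all(diff(spSeq) > 0))
  expect_error(statisticalPrecision(5, 0.1, makeHFit(a = -1), 0), "positive")
})

test_that("spatial resolution matches the closed form and Poisson scaling", {
  fit <- makeHFit(a = 1000)   # h(r) = 1e6/r^2 Hz
  dr <- spatialResolution(5, 0.1, fit, 0)
  # sigma = sqrt(4e4 * 0.1)/0.1 = 632.5 Hz; |h'| = 16 kHz/cm
  expect_equal(dr$value, 10 * 3 * (sqrt(4e4 * 0.1) / 0.1) / 16000,
               tolerance = 1e-12)
  expect_equal(dr$value, 1.19, tolerance = 1e-2)
  # doubling the window divides the resolution by sqrt(2)
  dr2 <- spatialResolution(5, 0.2, fit, 0)
  expect_equal(dr$value / dr2$value, sqrt(2), tolerance = 1e-12)
})

test_that("the derivative formula agrees with the brute-force displacement oracle", {
  set.seed(105)
  tested <- 0L
  while (tested < 50L) {
    a <- runif(1, 500, 5000); b <- runif(1, 0, a / 5)
    cc <- runif(1, 0, a / 500); d <- runif(1, 0, 0.3)
    fit <- makeHFit(a, b, cc, d)
    r <- runif(1, 3, 9); window <- runif(1, 0.05, 0.5)
    dcr <- runif(1, 0, 5e4)
    dr <- spatialResolution(r, window, fit, dcr)$value
    if (dr / (10 * r) >= 0.02) next   # deep linear regime: the first-order
    # formula deviates from the finite-displacement oracle by ~1.5 dR/r for
    # inverse-square-dominated profiles, so "dR << r" means a percent or two
    tested <- tested + 1L
    oracle <- bruteForceResolutionMm(fit, r, window, dcr)
    expect_lt(abs(dr - oracle) / oracle, 0.05)
  }
})

test_that("MDR crossing distance: analytic root, bounds and root-finder accuracy", {
  fit <- makeHFit(a = 1000)   # h = 1e6/r^2 Hz
  cross <- mdrCrossingDistance(fit, 1e4)
  expect_equal(cross$status, "ok")
  expect_equal(cross$distance_cm, 10, tolerance = 1e-6)

  expect_equal(mdrCrossingDistance(fit, 1e9)$status, "beyond-domain-near")
  expect_equal(mdrCrossingDistance(fit, 1)$status, "beyond-domain-far")

  # LDR-like profile: compare with the analytic root of a exp(-d r)/r^2 = MDR
  fitL <- makeHFit(a = 17.5, d = 0.22, domain = c(0.5, 6))
  target <- 1.2e3
  f <- function(r) 17.5e3 * exp(-0.22 * r) / r^2 - target
  analytic <- uniroot(f, c(0.5, 6), tol = 1e-12)$root
  expect_equal(mdrCrossingDistance(fitL, target)$distance_cm, analytic,
               tolerance = 1e-3)
})

test_that("compliance report evaluates the three criteria with margins", {
  # engineered system: h(10 cm) = 27 kHz, DCR = 36 kHz, HDR targets
  fit <- makeHFit(a = 2700, domain = c(2, 12))
  rep <- complianceReport(fit, 36e3, mode = "HDR")
  ck <- rep@checks
  sp <- ck$value[ck$criterion == "statistical_precision_frac"]
  expect_equal(sp, sqrt(2700 + 3600) / 2700, tolerance = 1e-12)
  expect_lt(sp, 0.05)
  expect_true(ck$pass[ck$criterion == "statistical_precision_frac"])

  # an MDR above the profile at the target distance fails the sensitivity
  repBad <- complianceReport(makeHFit(a = 50), 1e9, mode = "HDR")
  expect_false(repBad@checks$pass[1])

  # an ideal noiseless system passes everything
  repIdeal <- complianceReport(makeHFit(a = 1e5, domain = c(1, 12)), 1e3,
                               mode = "HDR")
  expect_true(all(repIdeal@checks$pass))
})

test_that("global rate rescaling moves SP and resolution as 1/sqrt(lambda)", {
  fit <- makeHFit(a = 2500, b = 100, c = 2, d = 0.08)
  lambda <- 4
  fitL <- makeHFit(a = 2500 * lambda, b = 100 * lambda, c = 2 * lambda,
                   d = 0.08)
  dcr <- 3e4
  sp1 <- statisticalPrecision(6, 0.1, fit, dcr)$value
  spL <- statisticalPrecision(6, 0.1, fitL, lambda * dcr)$value
  expect_equal(spL, sp1 / sqrt(lambda), tolerance = 1e-12)
  dr1 <- spatialResolution(6, 0.1, fit, dcr)$value
  drL <- spatialResolution(6, 0.1, fitL, lambda * dcr)$value
  expect_equal(drL, dr1 / sqrt(lambda), tolerance = 1e-12)
  # the MDR crossing is unchanged when profile and MDR scale together
  c1 <- mdrCrossingDistance(fit, 5e3)$distance_cm
  cL <- mdrCrossingDistance(fitL, 5e3 * lambda)$distance_cm
  expect_equal(c1, cL, tolerance = 1e-9)
})

test_that("the full simulated pipeline round-trips the ground truth", {
  src <- exampleHdrSource()
  spec <- sipmCatalog()[["PM1125"]]
  cfg <- simConfig(window = 0.1, threshold = 1.5, deadTime = 0, seed = 42L)
  ser <- simulateSourceScan(src, hdrGeometryGrid(), conversionK = 120, spec,
                            cfg)
  cal <- calibrateAtReference(ser, src)
  kTrue <- 120 * spec@octProb / 1e3
  expect_lt(abs(cal$k - kTrue), 3 * cal$kSE)

  ec <- energyCorrectionCurve(ser, src, cal$k)
  expect_lt(abs(ec$slope), 3 * ec$slopeSE)
  expect_lt(ec$chi2Reduced, 1.8)

  fit <- fitH(symmetrisePCR(ser, src, yMin = 2))
  expect_gt(fit@chi2Reduced, 0.5); expect_lt(fit@chi2Reduced, 1.8)
  # the fitted profile reproduces the symmetrised truth within 5% where the
  # specification is evaluated
  hTrue <- function(r) kTrue *
    doseRate(polarPoint(r, pi / 2), src)
  for (r in c(3, 5, 7))
    expect_lt(abs(hValue(fit, r) - hTrue(r)) / hTrue(r), 0.05)

  dcr15 <- applyThreshold(spec@dcr, spec, 1.5)
  rep <- complianceReport(fit, dcr15, mode = "HDR")
  expect_true(all(rep@checks$pass))
})
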