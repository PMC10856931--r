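# Counting-mode simulator: pile-up, dead-time response, threshold thinning,
# Poisson sampling and the scan generators.

test_that("pile-up probability follows the exponential gap law", {
  expect_equal(pileupProbability(4e6, 35e-9), 1 - exp(-0.14))
  expect_gt(pileupProbability(4e6, 35e-9), 0.10)
  expect_equal(pileupProbability(1e7, 0), 0)
  expect_equal(pileupProbability(1e6, 100e-9), 1 - exp(-0.1))
  expect_error(pileupProbability(-1, 1e-9), "non-negative")
})

test_that("analytic dead-time response: closed forms and monotone sub-linearity", {
  expect_equal(observedRate(5e6, 0), 5e6)
  expect_equal(observedRate(4e6, simConfig(deadTime = 35e-9)),
               4e6 * exp(-0.14))
  expect_equal(observedRate(4e6, 35e-9, model = "non-paralyzable"),
               4e6 / (1 + 0.14))
  R <- seq(1e5, 2e7, length.out = 50)
  for (m in c("paralyzable", "non-paralyzable")) {
    obs <- observedRate(R, 35e-9, model = m)
    expect_true(all(obs <= R))
    expect_true(all(obs > 0))
  }
  # the paralyzable curve turns over at R = 1/tau; below that it is monotone
  expect_true(all(diff(observedRate(seq(1e5, 2e7, length.out = 50),
                                    35e-9, model = "non-paralyzable")) > 0))
})

test_that("event-by-event Monte-Carlo agrees with the analytic dead-time curves", {
  tau <- 35e-9
  for (R in c(1e5, 1e6, 4e6, 1e7)) {
    tTot <- min(0.5, 2e5 / R)   # ~<= 2e5 arrivals per case
    set.seed(2024 + round(R / 1e5))
    for (m in c("paralyzable", "non-paralyzable")) {
      nMC <- mcDeadTimeCounts(R, tau, tTot, model = m)
      expected <- observedRate(R, tau, model = m) * tTot
      expect_lt(abs(nMC - expected), 3 * sqrt(expected) + 3,
                label = sprintf("MC vs analytic at R = %g (%s)", R, m))
    }
  }
})

test_that("threshold thinning: identity at 0.5 p.e., Bernoulli mean at 1.5 p.e.", {
  spec <- sipmSpec("toy", 0.2, 1e5, octProb = 0.26, sensitiveArea = 1)
  expect_equal(applyThreshold(1e6, spec, 0.5), 1e6)
  expect_equal(applyThreshold(1e6, spec, 1.5), 2.6e5)
  spec0 <- sipmSpec("no-oct", 0.2, 1e5, octProb = 0, sensitiveArea = 1)
  expect_equal(applyThreshold(1e6, spec0, 1.5), 0)
  expect_error(applyThreshold(1e6, spec, 2.5), "configuration")
})

test_that("simulated counts are Poisson with the configured mean and reproducible", {
  cfg <- simConfig(window = 0.1, deadTime = 0, nRepeats = 1000L, seed = 5L)
  m <- simulateCounts(1e5, 0, cfg)
  expect_equal(nrow(m), 1000L)
  # sample mean within 3 sigma of 1e4 counts
  expect_lt(abs(mean(m$gross_counts) - 1e4), 3 * sqrt(1e4 / 1000))
  # Poisson dispersion: variance/mean near 1
  fano <- var(m$gross_counts) / mean(m$gross_counts)
  expect_gt(fano, 0.9); expect_lt(fano, 1.1)

  # signal-free runs: gross and dark indistinguishable
  m0 <- simulateCounts(0, 5e4, cfg)
  expect_lt(abs(mean(m0$gross_counts) - mean(m0$dark_counts)),
            3 * sqrt(2 * 5e3 / 1000))

  # bit-identical under a fixed seed
  expect_identical(simulateCounts(1e5, 2e4, cfg), simulateCounts(1e5, 2e4, cfg))
})

test_that("cross-talk thinning shows up as the 1.5/0.5 p.e. rate ratio", {
  spec <- sipmCatalog()[["PM1125"]]
  rate <- 2e6
  cfg05 <- simConfig(window = 0.05, deadTime = 0, threshold = 0.5,
                     nRepeats = 200L, seed = 9L)
  cfg15 <- simConfig(window = 0.05, deadTime = 0, threshold = 1.5,
                     nRepeats = 200L, seed = 10L)
  n05 <- simulateCounts(applyThreshold(rate, spec, 0.5), 0, cfg05)$gross_counts
  n15 <- simulateCounts(applyThreshold(rate, spec, 1.5), 0, cfg15)$gross_counts
  ratio <- sum(n15) / sum(n05)
  se <- ratio * sqrt(1 / sum(n15) + 1 / sum(n05))
  expect_lt(abs(ratio - spec@octProb), 3 * se)
})

test_that("current-scan generator recovers the true sensitivity without dead time", {
  spec <- sipmCatalog()[["PM1125"]]
  cfg <- simConfig(window = 0.05, deadTime = 0, seed = 21L)
  scan <- simulateCurrentScan(5000, spec, cfg)
  expect_s4_class(scan, "CurrentScan")
  expect_equal(nrow(scanData(scan)), 13L)
  fit <- fitLinearity(scan)
  expect_true(all(fit@included))
  expect_lt(abs(fit@slope - 5000), 3 * fit@slopeSE)

  # zero sensitivity: PCR compatible with zero everywhere
  scan0 <- simulateCurrentScan(1e-9, spec, simConfig(window = 0.05, seed = 3L))
  pcr <- subtractDCR(scan0)
  expect_true(all(abs(pcr$pcr_khz) < 4 * pcr$sigma_khz))
})

test_that("dead time bends the scan and the gate excludes the highest currents", {
  spec <- sipmCatalog()[["S13360-1375"]]
  cfg <- simConfig(window = 1e-3, seed = 4L)   # default bench gate
  scan <- simulateCurrentScan(18187, spec, cfg)
  fit <- fitLinearity(scan)
  expect_false(all(fit@included))                   # top currents excluded
  expect_gt(fit@upperLimitPcr, 1e3)                 # upper limit in the
  expect_lt(fit@upperLimitPcr, 8e3)                 # few-MHz region
  # retained set is a prefix
  expect_true(all(diff(fit@included) <= 0))
})

test_that("source-scan generator reproduces the model field", {
  spec <- sipmSpec("ideal", 0.2, dcr = 1e4, octProb = 0.2, sensitiveArea = 1)
  ps <- sourceSpec(airKermaStrength = 1000, doseRateConstant = 1)

  # inverse square for a point source without dead time
  geom <- data.frame(r_cm = seq(1, 4, by = 0.5), theta_rad = pi / 2)
  ser <- simulateSourceScan(ps, geom, conversionK = 2000, spec,
                            simConfig(window = 1, deadTime = 0, seed = 31L))
  d <- scanData(ser)
  pred <- 2000 * doseRate(polarPoint(d$r_cm, d$theta_rad), ps) / 1e3
  expect_true(all(abs(d$pcr_khz - pred) < 4 * d$sigma_khz))

  # mean PCR at the reference point equals k * s_k * Lambda within 3 sigma
  ref <- data.frame(r_cm = rep(2, 50), theta_rad = pi / 2)
  # strictly speaking geometries repeat here: 50 independent windows at r0
  serRef <- simulateSourceScan(ps, ref, conversionK = 2000, spec,
                               simConfig(window = 1, deadTime = 0, seed = 32L))
  dRef <- scanData(serRef)
  kSkL <- 2000 * 1000 / 1e3   # kHz
  se <- sqrt(sum(dRef$sigma_khz^2)) / 50
  expect_lt(abs(mean(dRef$pcr_khz) - kSkL), 3 * se)
})

test_that("stem contamination is off by default and z-asymmetric when enabled", {
  src <- exampleHdrSource()
  spec <- sipmCatalog()[["PM1125"]]
  geom <- data.frame(y_cm = 2, z_cm = c(-3, -2, -1, 1, 2, 3))
  cfg <- simConfig(window = 0.5, deadTime = 0, threshold = 1.5, seed = 41L)

  ser <- simulateSourceScan(src, geom, 120, spec, cfg)
  d <- scanData(ser)
  dm <- d[order(d$z_cm), ]
  neg <- dm$pcr_khz[dm$z_cm < 0][3:1]   # |z| = 1, 2, 3
  pos <- dm$pcr_khz[dm$z_cm > 0]
  sig <- sqrt(dm$sigma_khz[dm$z_cm < 0][3:1]^2 + dm$sigma_khz[dm$z_cm > 0]^2)
  expect_true(all(abs(neg - pos) < 4 * sig))

  serStem <- simulateSourceScan(src, geom, 120, spec, cfg, stemCoef = 5e5)
  ds <- scanData(serStem)[order(scanData(serStem)$z_cm), ]
  negS <- ds$pcr_khz[ds$z_cm < 0][3:1]
  posS <- ds$pcr_khz[ds$z_cm > 0]
  expect_true(all(negS > posS))
})
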