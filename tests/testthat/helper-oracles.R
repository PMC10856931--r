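# Independent oracles used against the package implementations.

# Event-by-event Monte-Carlo dead-time counter for Poisson arrivals at rate
# `rate` observed over `tTotal` seconds. Returns the number of registered
# pulses. Paralyzable: a pulse is registered iff the gap since the previous
# arrival exceeds tau (any arrival re-extends the busy period).
# Non-paralyzable: arrivals within tau of the last *registered* pulse are
# dropped.
mcDeadTimeCounts <- function(rate, tau, tTotal,
                             model = c("paralyzable", "non-paralyzable")) {
  model <- match.arg(model)
  nArr <- stats::rpois(1, rate * tTotal)
  if (nArr == 0) return(0L)
  tArr <- sort(stats::runif(nArr, 0, tTotal))
  if (model == "paralyzable") {
    gaps <- diff(c(-Inf, tArr))
    return(sum(gaps > tau))
  }
  lastReg <- -Inf
  nReg <- 0L
  for (t in tArr) {
    if (t - lastReg > tau) {
      nReg <- nReg + 1L
      lastReg <- t
    }
  }
  nReg
}

# Subtended-angle oracle by explicit endpoint angles: the difference of the
# atan2 directions from the sensor to the two source endpoints (a different
# arithmetic route than the dot-product construction).
betaEndpointOracle <- function(r, theta, L) {
  sy <- r * sin(theta); sz <- r * cos(theta)
  a1 <- atan2(0 - sy, L / 2 - sz)
  a2 <- atan2(0 - sy, -L / 2 - sz)
  abs(a2 - a1)
}

# Brute-force spatial resolution: the smallest displacement delta towards
# the source for which |h(r - delta) - h(r)| (in Hz) equals three times the
# single-window Poisson rate uncertainty.
bruteForceResolutionMm <- function(fit, r, window, dcr) {
  sPCR <- sqrt((hValue(fit, r) * 1e3 + dcr) * window) / window
  f <- function(delta) abs(hValue(fit, r - delta) - hValue(fit, r)) * 1e3 -
    3 * sPCR
  10 * stats::uniroot(f, c(1e-9, 0.9 * (r - fit@domain[1] / 10)),
                      tol = 1e-10)$root
}

# An HFit built directly from known parameters (zero covariance), for
# closed-form checks that need no fitting step.
makeHFit <- function(a, b = 0, c = 0, d = 0, domain = c(0.5, 12),
                     covariance = matrix(0, 4, 4)) {
  cf <- c(a = a, b = b, c = c, d = d)
  dimnames(covariance) <- list(names(cf), names(cf))
  new("HFit", coefficients = cf, covariance = covariance,
      chi2Reduced = NA_real_, domain = domain)
}

# Exact-model scan series (no counting noise): PCR = k * doseRate with a
# fixed small Gaussian-free sigma, used where the analysis contract is
# checked against the model identity.
exactSeries <- function(src, geometry, k, sigmaFrac = 1e-3, window = 0.1,
                        threshold = 1.5) {
  geometry <- as.data.frame(geometry)
  if (all(c("y_cm", "z_cm") %in% names(geometry))) {
    p <- yzToPolar(geometry$y_cm, geometry$z_cm, 0)
    geometry$r_cm <- p@r; geometry$theta_rad <- p@theta
  }
  d <- doseRate(polarPoint(geometry$r_cm, geometry$theta_rad), src)
  geometry$pcr_khz <- k * d
  geometry$sigma_khz <- pmax(1e-9, sigmaFrac * k * d)
  geometry$window_s <- window
  scanSeries(geometry, threshold = threshold, sourceName = "exact-model")
}

# delta-method uncertainty of h(r) computed with a numeric parameter
# gradient (independent of the package's analytic gradients)
hSENumeric <- function(fit, r) {
  cf <- coef(fit)
  g <- vapply(seq_along(cf), function(i) {
    eps <- max(1e-6, abs(cf[i]) * 1e-6)
    up <- fit; up@coefficients[i] <- cf[i] + eps
    dn <- fit; dn@coefficients[i] <- cf[i] - eps
    (hValue(up, r) - hValue(dn, r)) / (2 * eps)
  }, numeric(1))
  sqrt(max(0, t(g) %*% vcov(fit) %*% g))
}
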