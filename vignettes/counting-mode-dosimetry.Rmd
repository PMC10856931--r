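---
title: "Counting-mode SiPM fibre dosimetry: models, figures of merit and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting-mode SiPM fibre dosimetry: models, figures of merit and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipmDosimetry)
```

## The measurement problem

Brachytherapy delivers dose from a radioactive seed implanted in or near a
tumour. A fibre dosimeter for this setting embeds a small scintillator in
the tip of a clear optical fibre; a slow scintillator (decay times of
order 500 us) turns each photon interaction into a train of single optical
photons, which a silicon photomultiplier (SiPM) counts one by one. The
photon counting rate (PCR) is then a surrogate for the dose rate, and the
entire analysis chain is counting statistics: Poisson signal and dark
counts, discriminator dead time, and optical cross-talk.

This package implements that chain end to end: the TG43-U1 dose-rate
model that provides the physical expectation, a counting-mode measurement
simulator that serves as the synthetic-data generator, the laboratory
figures of merit used to select a detector, and the pre-clinical analysis
that turns a phantom scan into a performance verdict against system
specifications.

## The TG43-U1 dose model

The dose rate around an encapsulated cylindrical source factorises as

$$\dot D(r,\theta) \;=\; s_k\,\Lambda\; F(r,\theta)\,
  \frac{G(r,\theta)}{G(r_0,\theta_0)}\; g(r),$$

with $r$ the distance from the source centre in cm and $\theta$ the polar
angle from the source long axis. The air-kerma strength $s_k$ and
dose-rate constant $\Lambda$ normalise the field so that
$\dot D(r_0, \theta_0) = s_k \Lambda$ at the reference point when
$g(r_0) = F(r_0,\theta_0) = 1$. The geometry factor for a line source of
active length $L$ is

$$G(r,\theta) = \frac{\beta}{L\,r\,\sin\theta} \quad (\theta \ne 0), \qquad
  G(r,0) = \left(r^2 - L^2/4\right)^{-1},$$

where $\beta$ is the angle the source segment subtends at the measurement
point; `geometryFactor()` computes $\beta$ from the endpoint vectors and
switches to the axial branch when $\sin\theta < 10^{-9}$ to avoid the
division blow-up, and returns the $1/r^2$ point-source limit for $L = 0$.
The radial dose function is the heuristic Laurent-polynomial form

$$g(r) = \Big(\sum_{n=-2}^{3} a_n r^n\Big) e^{-a_e r}.$$

The published typography of this expression is ambiguous about whether the
exponential sits inside or outside the sum; this package implements a
single exponential factor multiplying the polynomial. The two readings
coincide whenever a shared decay constant is meant, and the single-factor
form is the one that matches the cited heuristic's intent. $a_n$, $a_e$
are source- and afterloader-specific configuration, never constants; the
constructor warns when $g(r_0) \ne 1$ and deliberately does not
renormalise silently.

The anisotropy factor $F(r,\theta)$ has no analytic expression — it is
interpolated bilinearly from a look-up grid (`anisotropyTable()`, radii in
cm, angles in degrees, the common published convention). Queries outside
the table hull are clamped to the nearest edge with a warning, since
published grids rarely reach very small radii. Consensus tables for
commercial sources are licensed data and are not shipped;
`syntheticAnisotropy()` builds a smooth synthetic stand-in
($F = 1 - c(r)\cos^2\theta$) for simulation and tests.

Bench coordinates map to polar ones via `yzToPolar()`: the source travels
along z while the sensor sits at transverse distance y. The convention is
$\theta = \mathrm{atan2}(y, -(z_{src} - z_{sensor}))$, so a source
displaced towards positive z gives $\theta > \pi/2$. Only the symmetry
about the transverse plane is physical; the signed mapping is fixed so
that bench files are reproducible.

## The counting-mode simulator

The generator exists so that every analysis stage is testable without
proprietary instrument data. It models, per measurement point:

* **Poisson counting.** Gross counts are Poisson with mean
  (registered rate) x (window); each point carries an independent paired
  dark run, mirroring the protocol of re-measuring the dark rate after
  every irradiation so that slow afterglow cancels in the subtraction.
* **Threshold thinning.** At the 0.5 p.e. threshold every primary
  avalanche counts. At 1.5 p.e. a pulse passes only if the avalanche
  triggered at least one cross-talk neighbour — by the datasheet
  definition of the cross-talk probability $p_{OCT}$ this is Bernoulli
  thinning, so the mean registered rate is $p_{OCT} R$. Full
  Borel-multiplicity cross-talk chains are out of scope.
* **Dead time.** The default model is paralyzable,
  $R_{obs} = R\,e^{-R\tau}$ with $\tau$ = 35 ns (the shaped analog pulse
  and discriminator gate width): overlapping analog pulses extend the
  occupancy, which is what a leading-edge discriminator on 35 ns pulses
  does. The non-paralyzable alternative $R/(1+R\tau)$ is available for
  comparison. The associated pile-up probability is $1 - e^{-R\tau}$
  (13% at 4 MHz), consistent with the observed ~4 MHz linearity ceiling.
* **Stem contamination (optional, off by default).** A qualitative
  additive rate proportional to $\max(-z, 0)$ emulates the z-asymmetric
  spurious light picked up by the clear fibre when the source sits on the
  fibre side. No Cherenkov physics is modelled.

What the generator does **not** emulate: afterglow memory beyond the
paired-subtraction structure, temperature drifts of the dark rate,
waveform/pulse-shape effects, or real energy dependence of the
scintillator response (an energy drift can be injected linearly in tests).
Passing tests therefore demonstrate the statistical machinery and the
geometry handling, not the radiochromic fidelity of any real probe.

**Chosen study conditions.** The tube-current grid is the bench protocol:
0.05 mA steps to 0.3 mA then 0.1 mA steps to 1 mA (13 points). The
current-scan acquisition gate defaults to 1 ms: the published bench error
bars represent the spread of repeated short acquisitions, and a 1 ms
counter gate yields rate noise of tens of kHz, which is the level at which
dead-time curvature emerges from the noise in the few-MHz region as the
instrument showed. The pre-clinical grids are the phantom protocols: HDR,
sensor at y = 0.5, 1, 2, 3, 5 cm with the source stepped along z by
2.5 mm (widening to 5 mm beyond |z| = 2 cm, out to 5 cm); LDR, radial
steps of 1 mm from 5 to 20 mm on the transverse plane. Synthetic sources
(`exampleHdrSource()`, `exampleLdrSource()`) carry Ir-192-like and
I-125-like magnitudes; the LDR seed keeps the protocol-standard 1 cm
reference point (its dose-rate constant is defined there, and a 2 cm
calibration would drown in the 90 kHz dark rate), while HDR uses the 2 cm
normalisation point chosen to stay clear of pile-up and stem effects.

## Laboratory figures of merit

`subtractDCR()` forms $PCR_i = (N_{gross,i} - N_{dark,i})/\Delta t$ with
$\sigma_i = \sqrt{N_{gross,i} + N_{dark,i}}/\Delta t$; negative values are
kept and flagged, never clipped — their distribution is part of the
evidence that the subtraction is unbiased (the fitted intercept of a
signal-free scan must be compatible with zero).

The **minimum detectable rate** is the rate matching three Poisson
standard deviations of the dark counts in the window,

$$MDR = 3\sqrt{DCR/\Delta t},$$

so a 0.5 s window improves on a 0.1 s window by exactly $\sqrt 5$.
`figuresOfMerit()` reports the MDR both from the dark rate measured in the
scan's own dark runs and from the datasheet DCR.

The **linearity range** is gated by a reduced chi-squared criterion:
points are added in order of increasing current and the retained set is
the largest prefix whose weighted straight-line fit has
$\bar\chi^2 \le 2.7$ — approximately the 90% confidence level at one
residual degree of freedom. Residual degrees of freedom are
$n - 2$ (slope and intercept both fitted, the intercept being retained as
the zero-offset check). Only the highest currents are ever dropped:
pile-up bends the response down from above, and interior-point outlier
removal would change the question being asked. The parameter covariance
comes from the fixed Poisson weights, $(X^T W X)^{-1}$, not rescaled by
the residual dispersion — the weights are not nuisance estimates.

The **sensitivity** is the slope m of the retained linear fit
(kHz/mA); the smallest resolvable current step follows as $3\sigma/m$.

## Pre-clinical analysis

`calibrateAtReference()` gauges data against model at the source's
reference geometry: $k = PCR(r_0,\theta_0)/\dot D(r_0,\theta_0)$, using
the nearest scan point within a positional tolerance (default 0.05 cm and
2 degrees; an exact tie between two candidates is refused rather than
broken arbitrarily). `energyCorrectionCurve()` then forms per-point
ratios $PCR/(k\dot D)$ with a weighted linear fit in r — a scintillator
whose light yield drifts with the softening photon spectrum shows a
linear trend; the shared calibration-scale uncertainty is reported
separately rather than folded into each point.

`symmetrisePCR()` removes the modelled angular structure,

$$PCR_{Sym}(r) = PCR(r,\theta)\,
  \frac{G(r,\theta_0)}{G(r,\theta)}\,\frac{1}{F(r,\theta)},$$

collapsing all angles onto the transverse profile. This is the minimal
construction that maps the geometry factor to the transverse plane and
divides out the calculated anisotropy; it is the identity at
$\theta = \theta_0$ with $F \equiv 1$. Stem-affected rows are excluded by
the caller (`yMin`, default policy: drop y < 2 cm for HDR at the
1.5 p.e. threshold), since no stem correction is implemented.

The symmetrised profile is fitted by weighted nonlinear least squares to

$$h(r) = \left(\frac{a}{r^2} + \frac{b}{r} + c\right) e^{-d r},$$

the only reading of the published expression that is decreasing and
inverse-square dominated near the source. Initialisation: a from the
innermost point under a pure $1/r^2$ assumption, $b = c = 0$, d from the
log-slope of $r^2 PCR$ over the outer half of the points (robust to
repeated radii); d is bounded below at 0. The Levenberg-Marquardt
implementation of minpack.lm does the minimisation; the covariance is the
unscaled Poisson-weight one, and $\bar\chi^2$ uses $n - 4$ degrees of
freedom. A fitted profile that is not positive and decreasing over its
range triggers a warning — extrapolation of such a fit is not meaningful.

From the fit follow the three performance quantities, with uncertainties
propagated to first order from the parameter covariance:

* **Statistical precision**
  $SP(r;\Delta t) = \sqrt{N_{PCR} + N_{DCR}}/N_{PCR}$ with
  $N_{PCR} = h(r)\Delta t$, $N_{DCR} = DCR\,\Delta t$.
* **Spatial resolution**
  $\Delta R(r) = 3\sigma_{PCR}\,|\partial h/\partial r|^{-1}$, with
  $\sigma_{PCR}$ the single-window Poisson rate uncertainty including the
  dark rate, and the derivative taken analytically. The formula is the
  first-order version of "smallest displacement that moves the signal by
  $3\sigma$"; for inverse-square-dominated profiles the finite-displacement
  answer deviates by roughly $1.5\,\Delta R/r$, so the two agree to a few
  percent only in the $\Delta R \ll r$ regime (the package's tests verify
  5% agreement for $\Delta R/r < 0.02$).
* **MDR crossing distance**: the root of $h(r) = MDR$ by bisection.
  Within `mdrCrossingDistance()` the search is confined to the fitted
  domain by default; `complianceReport()` deliberately relies on the
  fitted model at the specification distances even beyond the scanned
  range, because extrapolating the verified fit is the stated assessment
  procedure (the alternative — refusing to extrapolate — would make the
  10 cm HDR criterion unevaluable from a 7 cm scan).

`complianceReport()` checks the three criteria against a per-mode
specification table (defaults: sensing distance 10 cm HDR / 3 cm LDR,
resolution 1 mm @ 5 cm HDR / 3 mm @ 3 cm LDR, precision 5% in 0.1 s @
10 cm HDR / 5% in 0.5 s @ 3 cm LDR).

## Worked example

```{r pipeline}
src  <- exampleHdrSource()
det  <- sipmCatalog()[["PM1125"]]
cfg  <- simConfig(window = 0.1, threshold = 1.5, seed = 42L)
scan <- simulateSourceScan(src, hdrGeometryGrid(), conversionK = 120,
                           det, cfg)
cal  <- calibrateAtReference(scan, src)
fit  <- fitH(symmetrisePCR(scan, src, yMin = 2))
fit
dcr15 <- applyThreshold(det@dcr, det, 1.5)
complianceReport(fit, dcr15, mode = "HDR")
```

## Numerical choices and degenerate inputs

* Angles are radians internally; anisotropy grids use degrees at I/O.
  Distances are cm, rates Hz internally and kHz at I/O, windows seconds.
* The axial branch of the geometry factor engages below
  $\sin\theta = 10^{-9}$; the sensor-inside-source region $r \le L/2$ is
  an error, not an extrapolation.
* Zero observed counts would give a zero Poisson uncertainty and an
  infinite weight; uncertainties are floored at one count per window.
* The $\bar\chi^2$ prefix gate requires at least three points and reports
  "no linear range" if even the first prefix fails.
* Simulations reseed only when a seed is supplied; scan-level generators
  seed once per run so that per-point draws stay within one stream.
* The c-d parameter pair of $h(r)$ becomes nearly degenerate when the
  plateau term lies below the noise floor (correlations up to 0.997 on
  narrow radial spans); first-order intervals for c are then optimistic.
  Parameter-level conclusions should be drawn from well-conditioned
  designs; function-value uncertainties remain reliable.

## Problem sizes

The package's own test suite simulates at the bench protocol sizes: 13
currents per scan, 133 HDR phantom geometries, 16 LDR radii, 200-seed
coverage studies for the linearity slope, and windows of 1500 repeats for
the dispersion properties. The full suite runs in well under a minute on
one core.

## Known limitations

* No Monte-Carlo radiation transport, scatter or heterogeneity
  corrections; capsule effects enter only through $F(r,\theta)$.
* No Cherenkov/stem physics: only an exclusion filter plus a qualitative
  contamination term in the generator.
* Cross-talk is Bernoulli thinning, not a multiplicity cascade; dark and
  signal processes are assumed independent Poisson.
* Shipped source parameters are synthetic stand-ins, clearly labelled;
  real analyses must supply the consensus data for their source and
  afterloader.
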