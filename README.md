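# sipmDosimetry

Analysis toolkit for scintillating-fibre brachytherapy dosimeters read out
by silicon photomultipliers (SiPMs) operated in photon-counting mode.

Brachytherapy treats tumours with a radioactive seed implanted in the
body; verifying in real time that the planned dose is actually delivered
requires a dosimeter small enough to sit in a catheter. One design embeds
a slow scintillator in the tip of an optical fibre and counts the
resulting single-photon train with a SiPM, so that the photon counting
rate (PCR) tracks the dose rate. This package provides, for physicists
developing or validating such systems:

* **`tg43` dose model** — the TG43-U1 formalism
  `D(r, theta) = s_k * Lambda * F(r, theta) * G(r, theta)/G(r0, theta0) * g(r)`,
  with the line-source geometry factor `G = beta / (L r sin theta)`, the
  radial dose function `g(r) = (sum a_n r^n) exp(-a_e r)` and bilinear
  anisotropy-table interpolation (`doseRate()`, `geometryFactor()`,
  `radialDoseFunction()`, `anisotropyFactor()`, `yzToPolar()`).
* **Counting-mode simulator** — Poisson photon and dark counts with
  paired dark runs, Bernoulli cross-talk thinning at the 1.5
  photo-electron threshold, paralyzable/non-paralyzable dead time
  (`simulateCurrentScan()`, `simulateSourceScan()`, `observedRate()`,
  `pileupProbability()`).
* **Laboratory figures of merit** — per-point dark subtraction, minimum
  detectable rate `MDR = 3 sqrt(DCR/dt)`, the reduced-chi-squared-gated
  linearity range (prefix fits until `chi2/dof > 2.7`, ~90% CL at one
  residual d.o.f.) and the sensitivity slope (`subtractDCR()`, `mdr()`,
  `fitLinearity()`, `figuresOfMerit()`).
* **Pre-clinical pipeline** — reference-point calibration, energy
  correction curves, angular symmetrisation onto the transverse plane,
  the radial profile fit `h(r) = (a/r^2 + b/r + c) exp(-d r)`,
  statistical precision `SP = sqrt(N_PCR + N_DCR)/N_PCR`, spatial
  resolution `dR = 3 sigma_PCR / |dh/dr|`, MDR crossing distance and a
  specification compliance report (`calibrateAtReference()`,
  `energyCorrectionCurve()`, `symmetrisePCR()`, `fitH()`,
  `statisticalPrecision()`, `spatialResolution()`,
  `complianceReport()`).

Datasheet parameters of the four candidate devices (KETEK PM1125/PM3325,
HAMAMATSU S13360-1350/-1375) ship as `sipmCatalog()`; the measured bench
reference figures as `benchmarkFigures()`. Shipped source descriptions are
synthetic stand-ins with realistic magnitudes (`exampleHdrSource()`,
`exampleLdrSource()`) — consensus radial-dose/anisotropy data for real
sources are configuration the user supplies.

## Worked example

Characterise a simulated PM1125 bench scan (X-ray tube currents 0.05-1 mA,
1 ms counting gate):

```r
library(sipmDosimetry)
spec <- sipmCatalog()[["PM1125"]]
scan <- simulateCurrentScan(6710, spec, simConfig(window = 1e-3, seed = 12L))
figuresOfMerit(scan, spec)
#> Detector 'PM1125': measured DCR 125.8 kHz
#>   MDR(0.1 s) = 3.36 kHz (datasheet: 3.35 kHz)
#>   MDR(0.5 s) = 1.50 kHz (datasheet: 1.50 kHz)
#>   sensitivity m = 6009 +/- 83 kHz/mA
```

The measured dark rate reproduces the 125 kHz datasheet value; the
0.1 s-window minimum detectable rate of 3.4 kHz is the rate matching three
Poisson standard deviations of those dark counts, and the 0.5 s value is
smaller by exactly `sqrt(5)`. The fitted sensitivity recovers the
simulation truth (6710 kHz/mA) up to the dead-time droop within the
retained linear range.

Run the pre-clinical HDR pipeline on a simulated phantom scan:

```r
src <- exampleHdrSource()
cfg <- simConfig(window = 0.1, threshold = 1.5, seed = 42L)
scan <- simulateSourceScan(src, hdrGeometryGrid(), conversionK = 120, spec, cfg)
fit <- fitH(symmetrisePCR(scan, src, yMin = 2))   # drop stem-affected y < 2 cm
complianceReport(fit, applyThreshold(spec@dcr, spec, 1.5), mode = "HDR")
#> Performance report (HDR mode):
#>   sensitivity_pcr_khz          23.31 >= 1.71 at 10 cm: PASS
#>   statistical_precision_frac   0.03205 <= 0.05 at 10 cm: PASS
#>   spatial_resolution_mm        0.8044 <= 1 at 5 cm: PASS
```

The extrapolated counting rate at 10 cm (23 kHz) sits far above the
1.7 kHz minimum detectable rate, the statistical precision in a 0.1 s
window at 10 cm is 3.2% against the 5% target, and the source displacement
resolvable at 3 sigma at 5 cm is 0.8 mm against the 1 mm target — an
all-pass HDR verdict for these study conditions.

A thin command-line wrapper over the same functions lives in
`inst/scripts/dosimeter.R` (`simulate`, `characterize`, `analyze-hdr`,
`analyze-ldr`).

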