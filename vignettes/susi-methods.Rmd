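---
title: "Spectral ultrasound quantification of engineered tissue constructs: models and methods"
author: "susi package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral ultrasound quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`susi` quantifies cell-seeded hydrogel constructs and bead phantoms from
raw high-frequency ultrasound RF data: bulk acoustics (thickness, speed of
sound, attenuation, volume), spectral inversion to effective scatterer
size, acoustic concentration, relative impedance, and deposited calcium
mass, and parametric overlays on B-mode images.  Because no public RF
dataset exists for this kind of acquisition, the package ships a forward
simulator with complete ground truth; every estimator is validated by
parameter recovery from simulated scans.

## Acquisition model

The emulated acquisition is a single-element 55 MHz probe (20--75 MHz
-6 dB band, 4.5 mm focal distance, 1.5 mm depth of focus) sampling RF at
420 MS/s, scanning laterally at 31 um per A-line and elevationally at
200 um per B-scan.  The sample sits in coupling fluid (sound speed
1480 m/s) above an agarose gel pad whose surface echo provides the
through-transmission reference; a reference scan without the sample is
acquired for calibration.  In the simulator the sample bottom sits 0.5 mm
above the gel pad; the gap cancels out of all time-of-flight estimates and
keeps the bottom-surface and gel-pad echoes separable.

## Bulk acoustics

**Surfaces.** Each A-line envelope (analytic-signal magnitude) is
thresholded relative to its maximum (default -15 dB); echoes are clusters
of above-threshold samples, and each surface time is the sub-sample
parabolic-refined envelope peak of its cluster.  Peaks rather than
threshold crossings are used because the peak of a symmetric pulse is
independent of pulse width to first order.  Per-A-line times are
aggregated by median for robustness to dropouts.

**Thickness and speed of sound** follow the substitution method.  With
round-trip times $t_{top}, t_{bot}, t_{gel}$ (sample present), $t_{ref}$
(sample absent) and fluid speed $c_f$:

$$L = \frac{c_f}{2}\left[(t_{bot}-t_{top}) + (t_{ref}-t_{gel})\right],
\qquad c_t = \frac{2L}{t_{bot}-t_{top}}.$$

These satisfy the identities $2L/c_t = t_{bot}-t_{top}$ and
$2L/c_f = (t_{ref}-t_{gel}) + (t_{bot}-t_{top})$ and are exact on
noise-free times (machine precision in the tests).

**Attenuation.** The frequency-dependent attenuation is estimated from
the insertion loss of the gel-pad echo,
$\alpha(f) = 20\log_{10}(|A_0(f)|/|A(f)|) / (2L)$ in dB/cm with the
round-trip path $2L$, where $|A(f)|$ and $|A_0(f)|$ are Hamming-windowed
gel-pad echo magnitude spectra with and without the sample.  The
attenuation coefficient in dB/(cm MHz) is the slope of a linear fit of
$\alpha(f)$ over 20--55 MHz (configurable), averaged across A-lines.
Simulated coefficients of 0.1--1.0 dB/(cm MHz) are recovered with < 10%
bias at 30 dB SNR.

**Volume.** Serial B-mode slices are thresholded; each A-line column is
filled between its boundary pixels and the largest laterally connected
run forms the per-slice cross-section; the volume is the rectangular-rule
sum of areas times the 200 um slice spacing (trapezoidal optional).  Two
boundary rules are available: `edge` (outermost above-threshold pixels;
exact for filled bright regions such as the synthetic-solid oracles) and
`peak` (envelope peaks of the first and last echo clusters; removes the
pulse-width smear when surfaces appear as thin echo bands in RF-derived
B-modes, the same rationale as the surface timing).  The pipeline default
is `peak`.  At desk scale (millimeter discs sampled at 200 um) the slice
discretization contributes a few percent of volume error; it shrinks with
construct size and slice density and largely cancels in volume ratios.

## Spectral model and inversion

Diffuse backscatter from monodisperse spherical scatterers (radius $a$,
number concentration $C$ per mm^3, relative impedance $Q$) is modeled with
a Gaussian form factor.  The calibrated power spectrum in dB over the
analysis band is

$$S(f) = 10\log_{10}(CQ^2) + 20\log_{10} V_s(a) + 10\,n\log_{10} f
 - G(c)\,a^2 f^2 + E,$$

with $V_s = \tfrac{4}{3}\pi a^3$, geometry exponent $n$ (4 for Rayleigh
spheres), $G(c) = (10 \cdot 0.827/\ln 10)(2000\pi/c)^2$ from the Gaussian
form factor $\exp(-0.827 k^2 a^2)$, and a system/shape constant $E$.
Windows are Hamming-tapered (256 samples, 50% overlap) sliding along each
A-line interior, each divided by the ensemble reference spectrum of the
gel-pad echo from the no-sample scan, which removes the transducer/system
response.  The analysis band is the -9 dB span of that reference spectrum
intersected with the transducer band; the mid-band fit is evaluated at
the band midpoint.

**Slope and MBF.** Ordinary least squares of $S(f)$ versus $f$ over the
band grid gives the raw slope $m'$ (dB/MHz) and mid-band fit $MBF'$ (dB).
Because $S(f)$ is linear in the regressors $\{\log_{10} f, f^2\}$, the
expected fitted slope is exactly linear in $n$ and $a^2$, so the radius
inversion

$$a = \sqrt{\frac{n\,S_{log} - m}{G\,S_{f2}}}$$

(with $S_{log}, S_{f2}$ the OLS slopes of the two regressors on the same
grid) is the exact algebraic inverse of the forward model; likewise the
$CQ^2$ inversion from the MBF.  Slopes beyond the zero-radius limit are
flagged non-physical (NA) and excluded from aggregation rather than
clipped, which would bias means.

**Attenuation correction.** Raw parameters are corrected as
$m = m' + 2\alpha z$ and $MBF = MBF' + 2\alpha z f_c$, with $\alpha$ in
dB/(cm MHz) and $z$ the window-center one-way depth below the top surface
in cm.  For the headline per-construct estimates, per-window calibrated
power spectra are first depth-compensated by $+2\alpha z f$ dB and then
averaged linearly (not in dB) across all windows.  Averaging power rather
than log-power makes the ensemble spectrum an unbiased estimate of the
model curve regardless of how few scatterers occupy each window, which
matters at late-timecourse concentrations of order 100 /mm^3.

**Completion and derived quantities.** With one of $C$ or $Q$ known,
$Q = \sqrt{CQ^2/C}$ or $C = CQ^2/Q^2$.  The equivalent scatterer number
is $CQ^2$ times the construct volume.  The relative impedance is the
fractional contrast $Q = (\rho_i c_i - \rho c)/(\rho c)$ against the ECM;
mineral deposited on a scatterer of volume $V_i = \tfrac43\pi a^3$ adds
mass without volume, so with the scatterer sound speed unchanged the
deposited calcium mass over $N_i$ scatterers is

$$M = N_i V_i \frac{\rho c}{c_i} (Q_i - Q_0),$$

the exact inverse of the forward mineralization model; $Q_i < Q_0$ is
reported as zero mass with a warning.

**The constant E.** $E$ collects scatterer-shape and system factors
(effective scattering volume, window gain, reference reflectivity) that
are not separable from a single calibrated acquisition and are not
published for this configuration.  It is calibrated once against the
simulator: eight noise-free, attenuation-free scans of the default
configuration (14 um scatterers, $C = 1000$ /mm^3, $Q = 0.6$) are run
through the standard analysis chain and $E$ is the mean difference
between measured and model MBF with the true $a$ and $CQ^2$ inserted
(`calibrateShapeParameter()`; frozen default -2.3363 dB).  $E$ is tied to
the default window settings; users changing window length or taper should
recalibrate.  In a laboratory setting the same one-time calibration would
be performed on a reference phantom of known bead size and concentration.

## Simulator

Each A-line sums, in the frequency domain (exact sub-sample delays),
specular echoes from the top surface, bottom surface and gel pad plus
echoes from scatterers Poisson-placed in an effective beam tube (default
radius 0.1 mm) spanning the sample thickness.  Each scatterer echo is the
transmit pulse (Gaussian envelope, -6 dB spectral width equal to the band
span) weighted by $Q V_s f^{n/2} \sqrt{\exp(-0.827 k^2 a^2)}$ and by the
amplitude attenuation $10^{-\alpha f z / 100}$ accumulated over its
round-trip in-sample path.  This is deliberately the same model family as
the inversion: the goal is estimator verification by recovery, and model
mismatch studies are out of scope.  Consequences: recovery tests
demonstrate correctness of the estimation chain (windowing, calibration,
regression, corrections, inversions, aggregation) under speckle and
receiver noise, but not robustness to non-Gaussian form factors,
polydispersity, beam diffraction, or nonlinear propagation, none of which
are modeled.

Design choices: scatterer phases arise from their continuous positions
(fully developed or sparse speckle as concentration dictates); a single
integer seed expands to deterministic per-A-line substreams so results
never depend on traversal order; receiver noise is additive white
Gaussian with standard deviation set from the closed-form expected
diffuse RMS over the sample interior (default SNR 30 dB), so the noise
level is uniform across A-lines and independent of individual Poisson
draws; interface reflectivities default to 0.1, well above diffuse
speckle so surface detection is exercised realistically.

## Study conditions encoded in the defaults

Phantom recovery uses 6, 10, 16 and 25 um bead diameters at
$C = 1000$ /mm^3 ($10^6$/ml), $Q = 0.6$, $\alpha = 0.5$ dB/(cm MHz),
SNR 30 dB, 2 mm thickness, 34 A-lines x 6 windows (>= 200 windows per
scan), 10 seeds.  Cell-like constructs use 14 um scatterers (the
day-0 effective cell diameter) at 2000 /mm^3 ($2\times10^6$/ml).  The
bundled timecourse (`exampleTimecourseConfig()`) is a 1 mm radius x 1 mm
disc compacting to 65% linear scale by day 7 (27.5% of initial volume,
inside the observed 25--30% compaction range) and stable thereafter,
concentration falling 1000 to 100 /mm^3 over 21 days, attenuation rising
0.3 to 0.5 dB/(cm MHz), and day-21 mineralization set to 40 ug/ml of the
day-21 construct volume.  Problem sizes (tens of A-lines, single-digit
slices, millimeter geometry) were chosen as the smallest at which the
window-count and ensemble-averaging assumptions of the method hold.

## Numerical details and edge cases

* Envelope: FFT analytic signal; all-zero slices map to a uniform
  B-mode floor rather than dividing by zero.
* Surface detection: A-lines with fewer than three echo clusters (or
  out-of-order times) are flagged invalid and excluded from the median;
  an all-invalid scan is an error.
* Spectral windows must clear each detected surface by a 40-sample
  margin plus half a window; bands narrower than 5 regression points are
  errors.
* The gel-pad echo analysis window must not overlap the construct
  interior; violated geometry is an error, not a silent bias.
* Non-physical inversions (negative radicand in the radius, non-positive
  argument in the concentration) propagate as NA and are excluded from
  ROI statistics.
* ROI statistics use 0.6 mm x 5.0 mm x thickness elements; ROIs with
  fewer than 5 windows are dropped with a message; construct-level means
  weight ROIs by window count.
* Fitted sound speeds outside 1300--1700 m/s and negative fitted
  attenuation produce warnings, not errors.

## Known limitations

* The inversion shares its scattering model with the simulator; accuracy
  on real tissue depends on how well a Gaussian form factor and a single
  effective scatterer population describe it.
* Absolute $C$, $Q$ and calcium estimates require one known quantity
  (cell count or impedance), exactly as in the laboratory workflow.
* The effective beam tube ignores diffraction and focusing; $E$ absorbs
  the resulting scale factor, so cross-instrument transfer of $E$ is not
  meaningful without recalibration.
* B-mode log compression here is a standard 20*log10 envelope map; the
  vendor grayscale transform it stands in for is defined only by citation
  in the source literature.
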