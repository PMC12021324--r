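---
title: "Gradient-chain characterization and 4D UTE reconstruction: methods"
author: "girfute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient-chain characterization and 4D UTE reconstruction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(girfute)
```

# The problem

Ultrashort-echo-time (UTE) imaging samples k-space center-out, starting on
the ramp of the readout gradient, so that short-T2* tissue such as lung
parenchyma still carries signal. The k-space position assigned to each
sample is the time integral of the gradient waveform; any discrepancy
between the programmed (nominal) and physically produced gradient therefore
mis-places samples, and the error is worst exactly where UTE is most
sensitive -- near the k-space center at the start of every spoke. On
MR-Linac systems with split gradient coils the settling behavior of the
gradient chain (amplifier bandwidth, eddy currents, timing offsets) makes
this a first-order problem: uncorrected UTE images show halos, signal loss
and shading.

The package implements the full chain that addresses this:

1. **Characterization.** The gradient chain is modeled as linear and
   time-invariant (LTI), summarized by a complex transfer function
   H(f) between nominal and produced gradient (the gradient system
   transfer function, GSTF; its inverse transform is the impulse response,
   GIRF). H is measured with the *thin-slice method*: two thin slices at
   positions +/- D from isocenter are excited and their signal phase is
   recorded under triangular test gradients, using the relation
   phi(t) = gamma D integral g(t') dt'. Triangles of 21 amplitudes fill
   the spectral nulls of one another, and H is the least-squares ratio
   H(f) = sum_i Conj(Gnom_i) Gmeas_i / sum_i |Gnom_i|^2.
2. **Correction.** Nominal readout gradients are resampled to a fine
   raster, Fourier transformed, multiplied by the (noise-filtered) GSTF,
   transformed back and re-integrated; reconstruction then uses the
   corrected sample positions.
3. **Reconstruction.** Stack-of-stars golden-angle data are transformed
   along the Cartesian kz axis, self-navigated from the k-space center,
   sorted into overlapped respiratory bins, and reconstructed by adjoint
   gridding (motion-averaged) or by nonlinear conjugate-gradient
   compressed sensing with a temporal total-difference penalty
   (respiratory-resolved, 4D).
4. **Simulation.** An analytic chain model, a synthetic thin-slice
   generator and a breathing digital phantom provide ground truth for
   every stage, so that the whole pipeline is testable without scanner
   access.

# Conventions and phase combinations

All internal quantities are SI (T/m, s, m^-1, Hz); gamma = 2.675222e8
rad/s/T, gamma-bar = 42.5775 MHz/T. Spoke azimuths advance by the golden
angle, 111.2461 degrees. k-space positions are obtained from gradient
series by the trapezoidal rule; corrected and nominal positions always go
through the *same* integration and sampling-time interpolation path, so an
identity transfer function is a no-op by construction.

The thin-slice processing removes nuisance phases by symmetry:

* polarity half-difference (phi+ - phi-)/2 cancels static off-resonance
  and concomitant terms;
* slice half-difference over the two slices at +/- D isolates the
  first-order (trajectory-relevant) phase with lever arm D per slice;
* slice half-sum isolates the zeroth-order (spatially uniform) phase. It
  is returned for inspection but deliberately not used downstream: the
  package corrects first-order effects only, matching the center-out
  argument that uniform phase accrues negligibly by the time low k is
  sampled.

In the simulator, zeroth-order (B0) settling terms scale with the signed
applied gradient, so they survive the polarity combination and cancel in
the slice difference -- the same order in which the measurement removes
them. Coil compression (SVD across channels, dominant component retained
by default), first-sample phase alignment, complex averaging and 1-D
unwrapping (pi threshold, warning on saturated jumps) follow in that
order; the averaging is performed after per-average alignment so that
repetitions add coherently.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| triangle amplitudes | 21, 4--15 | mT/m | spectral coverage of the estimator |
| slew rate | 65 | mT/m/ms | ramp rate of test pulses and readout |
| slice offset D | 20 | mm | phase lever arm |
| analysis window | 30 | ms | spectral resolution df = 1/window = 33.3 Hz |
| thin-slice dwell | 0.6 | us | 1.67 MHz sampling |
| smoothStart | 6 | kHz | Gaussian smoothing applied beyond this |
| gaussSd | 0.6 | kHz | smoothing kernel SD |
| tukeyTaper | 0.1 | -- | band-edge taper against ringing |
| resampleDt / pad | 0.1 / 5000 | us | correction raster and zero padding |
| nBins / overlap | 5 / 0.5 | -- | respiratory states, shared halves |
| nIter | 15 | -- | conjugate-gradient iterations |
| lambdaFrac | 0.05 | -- | penalty weight, fraction of peak adjoint image |
| centerSamples | 9 | -- | navigator points nearest the k-space center |
| navWindow | 41 | spokes | background moving-average width (~36 s) |

The moving-average width is not fixed by the protocol; 41 spoke blocks
(about 36 s at the 0.887 s motion sampling interval) is long against a
breath and short against scanner drift. The coil-quality measure is a
spectral-concentration score (fraction of non-DC navigator power inside
0.1--0.5 Hz); the lower-scoring half of the coils is discarded before
principal component analysis. The first component is used unless it fails
an autocorrelation periodicity check, in which case the second is taken
and flagged -- an automated stand-in for the visual inspection such
pipelines otherwise require. The surrogate sign is fixed so that the most
frequent extreme (the end-expiration plateau) is the maximum, implemented
as a non-positive skewness convention.

# Sequence construction

The multi-echo UTE readout is built as a center-out half spoke sampled
during the ramp (TE1) followed by bipolar full-spoke gradient echoes. At
the protocol settings (500 mm field of view, matrix 332, 865 Hz/pixel,
oversampling 2) this reproduces the published accounting exactly: readout
gradient 13.49 mT/m, 392 samples for the first echo (332 half-spoke
samples plus half the ramp samples) and 664 for the later echoes. The
configured echo times are treated as *requested minima*: a contiguous
bipolar train at the 65 mT/m/ms slew limit reaches the second echo about
2 us later than the nominal table value (the printed times are rounded
below feasibility), and the achieved times are returned alongside the
waveforms. Breakpoints are snapped to the waveform raster so the sampled
series represents the piecewise-linear waveform exactly. The kz axis is
ideal Cartesian throughout; variable-duration slice encoding is not
modeled.

# Numerical choices

* **Differentiation.** Measured gradients are the central finite
  difference of the isolated phase (one-sided at the ends). On linear
  ramps this is exact; at the three slope discontinuities of a triangle
  the truncation error is slew x dwell / 2, and the induced transfer-
  function bias at 6 kHz and 0.6 us dwell is ~1e-4 -- an order below the
  1e-3 identification budget.
* **FFT lengths.** All spectral operations zero-extend to 5-smooth
  composite lengths; the extra zeros only deepen the existing pad.
* **Conjugate symmetry.** The Tukey window is evaluated as a symmetric
  function of |f| over the represented band (an index-based window is
  half-a-bin asymmetric on an even grid), the unpaired Nyquist bin is
  forced real, and any residual asymmetry of a supplied transfer function
  is symmetrized with a warning; the imaginary residual after the inverse
  transform is asserted below 1e-6 of the signal norm.
* **Filtering scope.** The Gaussian-plus-Tukey preparation is meant for
  noisy measured spectra. It is applied by default in trajectory
  correction, but the pure LTI application (filter = FALSE) is used when
  an analytic transfer function must match a time-domain convolution
  oracle exactly: smoothing a one-pole response above 6 kHz biases it at
  the 0.5% level by design, which is desired for noise and undesired for
  oracles.
* **Gridding.** The type-2/type-1 non-uniform transforms use Kaiser-
  Bessel interpolation (width 8, 2x oversampled grid) built so that the
  adjoint is the exact transpose of the forward; adjointness holds to
  machine precision and accuracy against direct summation is ~1e-7.
* **Density compensation.** Radial ramp weights with the local arc-length
  spacing along each spoke (so the center crossing of a full spoke keeps a
  finite spacing), per-spoke angular Voronoi shares (golden-angle gaps are
  unequal), and a small-disk floor for the k-space-center sample of
  center-out spokes. Weights are used for adjoint initialization, not
  inside the iterative solver.
* **Compressed sensing.** Nonlinear conjugate gradient (Polak-Ribiere)
  with a backtracking Armijo line search; the penalty is the first-order
  temporal difference across bins under an epsilon-smoothed absolute value
  (epsilon = 1e-6 of the data scale). Steps are only accepted on descent,
  so the recorded objective is nonincreasing by construction. The weight
  lambda is 5% of the peak per-bin adjoint image, which makes the solution
  exactly homogeneous of degree one in the data.
* **Coil maps.** A low-resolution ratio method (heavily apodized central
  k-space, per-coil image over root-sum-of-squares, support-masked)
  replaces eigenvector-based self-consistent estimation; for the smooth
  simulated profiles it recovers maps to a few percent. Because maps are
  normalized, the combined reconstruction estimates rss x object, and all
  image comparisons use the coil-weighted reference.
* **Edge metric.** The line-spread function is the Gaussian fit to the
  derivative of a magnitude profile; orientation and scale are
  canonicalized before the nonlinear fit so reversal/scaling invariance
  holds to the optimizer's resolution (~1e-7 relative; a nonlinear
  least-squares optimum cannot be pinned tighter than ~sqrt(machine
  epsilon) in its parameters). Derivative lobes below 30% of the peak are
  treated as artifact rather than as a second edge, which lets the metric
  operate on distorted (uncorrected) images; widths at or below two pixel
  pitches are flagged as resolution-limited.

# What the simulator does and does not emulate

The thin-slice generator reproduces the measurement geometry (two 3-mm
slices at +/- 20 mm), the triangle family, polarity cycling, per-coil
gain/phase, static off-resonance, zeroth-order settling and complex
Gaussian noise, with the produced gradient computed analytically in the
frequency domain on a 0.1 us raster. Its defaults follow the protocol
except the repetition count: 100 averages at full protocol size is tens of
gigabytes of raw signal, so the default is 2 and noise-free validations
use 1 -- for noiseless identification the average count is immaterial.

The breathing phantom is an ellipse-based torso with low-intensity lungs,
a liver dome whose diaphragm boundary is displaced by
peakDisplacement x s(t), a bright disk for edge metrics, and smooth
polynomial coil profiles. The surrogate s(t) = sin^4(pi t / period) has
the long end-expiration plateau of free breathing; one spoke angle is
acquired per kz block, so the surrogate is sampled every trMotion x nKz
seconds (0.887 s at protocol settings). Deliberately *not* modeled:
relaxation and off-resonance contrast, through-plane motion, hysteresis
(inspiration and expiration at equal displacement are identical), slab
excitation profiles, and gradient non-LTI behavior. Passing tests
therefore demonstrate the correctness of the estimation, correction and
reconstruction machinery under the stated physics -- not robustness to
physiology or hardware effects outside the LTI model.

Two observations from the synthetic data are worth noting. First, the
navigator samples away from the exact k-space center pick up a golden-
angle angular modulation of an anisotropic object (0.309 cycles per
spoke); coil scoring and principal component analysis suppress it, and the
exact-center sample is immune, but single-coil navigator spectra show the
leakage. Second, the displacement "between extreme bins" is validated
against the mean injected displacement over each bin's member spokes:
equal-count quantile bins of a plateaued breathing trace never reach the
full peak-to-peak amplitude, so the raw peak would be the wrong oracle.

# Problem sizes

The test-suite and the acceptance script run at desk scale, chosen to keep
the full suite in minutes while exercising every protocol rule: chain
identification at the full 21-triangle, 30-ms, 0.6-us protocol (1--2
coils, one average, noiseless); trajectory-correction benefit on a 128^2
phantom with 664 spokes and 8 coils; the 4D pipeline on a 64^2 phantom
with 664 spokes, 0.887 s motion sampling, 5 bins and 15 iterations. The
in-plane matrix is the only quantity scaled down from the protocol (332);
all timing, binning and regularization settings are the protocol values.

# Known limitations

Zeroth-order phase is extracted but no zeroth-order data correction is
applied; the kz/partition axis is ideal; only first-order spatial terms
are characterized; bins are phase-ordered without a cyclic penalty, so
respiratory hysteresis is invisible by design; the coil-quality score and
the component-selection fallback are automated surrogates for visual
checks; and trajectory correction assumes the chain is strictly LTI --
amplitude-dependent or thermal effects fold into the residual.
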