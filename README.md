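# girfute

Gradient system transfer function (GSTF) estimation and 4D UTE
reconstruction for MR-Linac imaging, in R.

Ultrashort-echo-time (UTE) MRI samples k-space center-out during the ramp
of the readout gradient, which makes it exquisitely sensitive to the
difference between the gradient waveform a sequence *requests* and the one
the gradient chain *produces*. Modeling the chain as a linear
time-invariant system, that difference is captured by the first-order
gradient system transfer function H(f) — the complex frequency response
relating nominal to produced gradients (its inverse Fourier transform is
the gradient impulse response function, GIRF). `girfute` is for MR
physicists and reconstruction researchers who want the complete chain in
one scriptable package:

* **measure** H(f) from thin-slice acquisitions: two slices at ±D about
  isocenter, triangular test gradients of 21 amplitudes and both
  polarities, signal phase φ(t) = γ·D·∫g(t′)dt′, and the least-squares
  estimator

      H(f) = Σᵢ conj(Gnom,ᵢ(f)) · Gmeas,ᵢ(f) / Σᵢ |Gnom,ᵢ(f)|²  ;

* **correct** center-out stack-of-stars trajectories by applying the
  (Gaussian-smoothed, Tukey-tapered) GSTF to the nominal readout
  gradients in the frequency domain and re-integrating k(t) = γ̄∫g;

* **reconstruct** motion-averaged and respiratory-resolved (4D) images:
  k-space-center self-navigation, overlapped equal-count respiratory
  binning (5 bins, 50% overlap), radial density compensation, coil maps,
  and compressed sensing solving
  argmin_d ‖F(d, C) − y‖² + λ‖S(d)‖₁ with a temporal total-difference
  penalty and 15 conjugate-gradient iterations;

* **simulate** everything: an analytic settling-chain model
  H(f) = e^(−i2πfτ)·(1 − Σₖ αₖ·i2πfτₖ/(1 + i2πfτₖ)), synthetic
  thin-slice signal sets, and a breathing digital phantom with multi-coil
  golden-angle stack-of-stars sampling — so every stage of the pipeline
  has a ground-truth oracle.

The compiled core is a Kaiser–Bessel gridding NUFFT (type 1/2) with an
exactly adjoint construction and a direct-summation oracle for validation.

## Worked example

Identify a gradient chain (2 µs delay plus one 1% eddy term with a 100 µs
time constant) from simulated thin-slice data, then compare the estimate
with the ground truth:

```r
library(girfute)

chain <- GradientChainModel(delay = 2e-6, eddyAmp = 0.01, eddyTau = 100e-6)
tri   <- makeTriangleSet(21, 4e-3, 15e-3, 65, 6.4e-6)
tri
#> TriangleSet: 21 triangles, 4-15 mT/m, slew 65 mT/m/ms

ds <- simulateThinSlice(chain, tri, nCoils = 2, nAverages = 1, dwell = 1.2e-6)
H  <- estimateGstf(tri,
                   phaseToGradient(isolatePhaseComponents(condenseSignals(ds))),
                   window = 30e-3, pulseStart = ds@pulseStart)
H
#> Gstf [estimated]: 25000 frequencies, df 33.33 Hz, band +/- 417 kHz (901 characterized)

compareGstfs(chainTransfer(chain, freqGrid(H)), H, fitBand = 2e3)
#> GSTF comparison report
#>   |f| <=    2 kHz: max |dH| 3.85e-05, max |d arg H| 2.29e-06 rad
#>   |f| <=    6 kHz: max |dH| 0.000348, max |d arg H| 8.08e-06 rad
#>   |f| <=   15 kHz: max |dH| 0.0022, max |d arg H| 5.6e-05 rad
#>   DC group-delay difference: 0.0002348 us
```

The 30 ms analysis window gives the 33.3 Hz spectral resolution; the
estimate matches the analytic chain to 3.5 × 10⁻⁴ below 6 kHz, and the
residual DC group-delay error is well below a nanosecond. The same
estimate drives trajectory correction (`correctTrajectory`) and the 4D
pipeline (`extractNavigator`, `deriveSurrogate`, `binSpokes`,
`reconAdjoint`, `reconCs`); `vignettes/girfute-methods.Rmd` documents the
model, the parameter choices and the numerical design, and
`inst/cli/girfute.R` exposes the stages as shell commands.

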