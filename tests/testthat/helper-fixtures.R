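# Shared fixtures and independent oracles, all generated in code.

# Small triangle family for fast tests.
tinyTriangles <- function(n = 5L, dt = 6.4e-6) {
    makeTriangleSet(n, 4e-3, 15e-3, 65, dt)
}

# The analytic settling chain used for identification checks:
# delay 2 us, one eddy term (amplitude 0.01, time constant 100 us).
idChain <- function() {
    GradientChainModel(delay = 2e-6, eddyAmp = 0.01, eddyTau = 100e-6)
}

# Imaging sequence scaled to a small matrix (single center-out echo).
quickSeqConfig <- function(n = 64L, fov = 0.5, nSpokes = 664L,
                           dwell = 1 / (865 * 332 * 2), tes = 0.176e-3,
                           nKz = 103L, trMotion = 8.61e-3) {
    SequenceConfig(fov = fov, matrixSize = n, nSpokes = nSpokes, nKz = nKz,
                   tes = tes, trMotion = trMotion, dwell = dwell)
}

# Smooth (effectively band-limited) gradient pulse: sin^4 lobe, zero at
# the ends with continuous low-order derivatives (spectrum decays ~f^-5).
smoothPulse <- function(dt = 0.1e-6, dur = 400e-6, amp = 10e-3) {
    nS <- round(dur / dt)
    GradientWaveform("X", amp * sin(pi * (0:nS) / nS)^4, dt = dt)
}

# The exact DC-centered frequency grid applyGstf uses for a waveform under
# a given filter configuration (resample, pad, composite FFT length).
applyGstfGrid <- function(w, cfg = GstfFilterConfig()) {
    wr <- resampleWaveform(w, cfg@resampleDt, cfg@pad)
    n <- stats::nextn(length(wr@samples), c(2L, 3L, 5L))
    sort(fftFreqCentered(n, cfg@resampleDt))
}

# Exact continuous convolution of a piecewise-linear (sampled) waveform
# with the one-pole low-pass kernel h(t) = (1/tau) exp(-t/tau): the
# linear-interpolation exponential integrator, evaluated recursively.
onePoleConvOracle <- function(g, dt, fc) {
    tau <- 1 / (2 * pi * fc)
    a <- exp(-dt / tau)
    n <- length(g)
    gPrev <- c(0, g[-n])
    slope <- (g - gPrev) / dt
    b <- g - a * gPrev - slope * tau * (1 - a)
    as.numeric(stats::filter(b, a, method = "recursive"))
}

# Root-sum-of-squares coil-weighted ground truth for recon comparisons.
rssReference <- function(phantom, s = 0) {
    rss <- sqrt(apply(Mod(phantom@coilSens)^2, c(1, 2), sum))
    phantomFrame(phantom, s) * rss
}

# Manual thin-slice dataset: fill all (amp, polarity, slice, coil, avg)
# series from a function f(eps, sg, coil) returning a complex series.
manualThinSlice <- function(f, nSamp = 256L, nCoils = 1L, nAvg = 1L,
                            nAmp = 2L, dwell = 1e-5) {
    tri <- makeTriangleSet(nAmp, 4e-3, 8e-3, 65, 6.4e-6)
    sig <- array(0i, c(nAmp, 2L, 2L, nCoils, nAvg, nSamp))
    for (i in seq_len(nAmp)) for (p in 1:2) for (s in 1:2)
        for (co in seq_len(nCoils)) for (a in seq_len(nAvg))
            sig[i, p, s, co, a, ] <- f(c(1, -1)[p], c(1, -1)[s], co)
    new("ThinSliceDataset", signals = sig, dwell = dwell,
        sliceOffset = 0.02, sliceThickness = 3e-3, triangles = tri,
        axis = "X", pulseStart = 0)
}
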