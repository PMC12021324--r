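# Spectral filtering of the GSTF and its application to waveforms and
# trajectories.

test_that("spectral filtering smooths only beyond the passband edge", {
    f <- seq(-20e3, 20e3, by = 100)
    h <- rep(1 + 0i, length(f))
    cfg <- GstfFilterConfig()
    out <- filterGstf(Gstf("X", f, h), cfg)
    flat <- abs(f) <= cfg@smoothStart
    expect_lt(max(Mod(out@H[flat] - 1)), 1e-12)

    # unit step at 7 kHz: smoothed edge equals the direct discrete
    # convolution with the same truncated Gaussian kernel
    hs <- ifelse(f >= 7e3, 1 + 0i, 0 + 0i)
    out2 <- filterGstf(Gstf("X", f, hs), cfg)
    df <- 100
    nk <- 2L * ceiling(5 * cfg@gaussSd / df) + 1L
    kern <- dnorm(seq(-(nk %/% 2L), nk %/% 2L) * df, sd = cfg@gaussSd)
    kern <- kern / sum(kern)
    half <- nk %/% 2L
    xp <- c(rep(0, half), Re(hs), rep(1, half))
    oracle <- as.numeric(stats::filter(xp, kern,
                                       sides = 2L))[(half + 1L):(half + length(f))]
    tuk <- tukeyWindowFreq(f, cfg@tukeyTaper)
    sel <- f > 6e3 & f < 12e3           # inside the flat Tukey region
    expect_lt(max(abs(Re(out2@H[sel]) - oracle[sel] * tuk[sel])), 1e-6)
    # below the smoothing threshold the step stays untouched (up to Tukey)
    selLo <- abs(f) < 6e3
    expect_equal(Re(out2@H[selLo]), Re(hs[selLo]) * tuk[selLo],
                 tolerance = 1e-12)

    coarse <- Gstf("X", seq(-20e3, 20e3, by = 1e3), rep(1 + 0i, 41L))
    expect_error(filterGstf(coarse, cfg), "undersampled")
})

test_that("identity transfer is a no-op for band-limited waveforms", {
    w <- smoothPulse()
    f <- seq(-5e6, 5e6, by = 500)
    H1 <- Gstf("X", f, rep(1 + 0i, length(f)))
    out <- applyGstf(w, H1)                       # full default filter path
    wr <- resampleWaveform(w, 0.1e-6, 5e-3)
    nPad <- round(5e-3 / 0.1e-6)
    core <- wr@samples[(nPad + 1L):(length(wr@samples) - nPad)]
    expect_lt(relErr(out@samples, core), 1e-9)
})

test_that("a pure-delay transfer shifts the waveform by the delay", {
    w <- smoothPulse()
    tau <- 5e-6
    f <- seq(-5e6, 5e6, by = 500)
    Hd <- Gstf("X", f, exp(-1i * 2 * pi * f * tau))
    out <- applyGstf(w, Hd, filter = FALSE)
    wr <- resampleWaveform(w, 0.1e-6, 5e-3)
    nPad <- round(5e-3 / 0.1e-6)
    core <- wr@samples[(nPad + 1L):(length(wr@samples) - nPad)]
    lags <- -100:100
    cc <- vapply(lags, function(l) {
        idx <- seq_along(core)
        sh <- idx - l
        ok <- sh >= 1L & sh <= length(core)
        sum(out@samples[idx[ok]] * core[sh[ok]])
    }, numeric(1))
    expect_identical(lags[which.max(cc)], 50L)    # 5 us at 0.1 us raster
})

test_that("frequency-domain application matches exact time-domain convolution", {
    w <- tinyTriangles(3L)@waveforms[[3L]]
    fc <- 3e3
    cfg <- GstfFilterConfig()
    wr <- resampleWaveform(w, cfg@resampleDt, cfg@pad)
    oracle <- onePoleConvOracle(wr@samples, cfg@resampleDt, fc)
    f <- applyGstfGrid(w, cfg)
    Hp <- Gstf("X", f, 1 / (1 + 1i * f / fc))
    out <- applyGstf(w, Hp, cfg, filter = FALSE)
    nPad <- round(cfg@pad / cfg@resampleDt)
    oracleCore <- oracle[(nPad + 1L):(length(wr@samples) - nPad)]
    expect_lt(relErr(out@samples, oracleCore), 1e-6)
})

test_that("application is linear and respects the passive energy bound", {
    w1 <- smoothPulse(dt = 1e-6, dur = 300e-6, amp = 8e-3)
    w2 <- smoothPulse(dt = 1e-6, dur = 300e-6, amp = 5e-3)
    w2@samples <- rev(w2@samples) * seq(0, 1, length.out = length(w2@samples))
    w2@samples[length(w2@samples)] <- 0
    f <- seq(-5e6, 5e6, by = 500)
    Hp <- Gstf("X", f, 1 / (1 + 1i * f / 4e3))
    lin <- initialize(w1, samples = 2 * w1@samples - 3 * w2@samples)
    a <- applyGstf(lin, Hp, filter = FALSE)
    b1 <- applyGstf(w1, Hp, filter = FALSE)
    b2 <- applyGstf(w2, Hp, filter = FALSE)
    expect_lt(relErr(a@samples, 2 * b1@samples - 3 * b2@samples), 1e-9)
    # |H| <= 1 everywhere: output L2 norm cannot exceed the input norm
    wr <- resampleWaveform(w1, 1e-7, 5e-3)
    expect_lte(sqrt(sum(b1@samples^2)),
               sqrt(sum(wr@samples^2)) * (1 + 1e-9))
})

test_that("asymmetric transfer functions are symmetrized with a warning", {
    w <- smoothPulse(dt = 1e-6, dur = 300e-6)
    f <- seq(-5e6, 5e6, by = 500)
    hBad <- exp(-1i * 2 * pi * pmax(f, 0) * 3e-6)   # one-sided phase
    expect_warning(applyGstf(w, Gstf("X", f, hBad), filter = FALSE),
                   "conjugate symmetry")
})

test_that("identity transfer leaves the trajectory at its nominal positions", {
    cfg <- quickSeqConfig(n = 32L, nSpokes = 8L)
    sq <- makeUteSequence(cfg)
    f <- seq(-5e6, 5e6, by = 1e3)
    H1 <- Gstf("X", f, rep(1 + 0i, length(f)))
    corr <- correctTrajectory(sq, H1, H1, filter = FALSE)
    expect_lt(max(abs(corr@kx - sq$traj@kx)), 1e-9)
    expect_lt(max(abs(corr@ky - sq$traj@ky)), 1e-9)
    expect_error(correctTrajectory(list(gx = sq$gx), H1, H1), "must provide")
})

test_that("chain-distorted trajectories match a time-domain oracle", {
    cfg <- quickSeqConfig(n = 32L, nSpokes = 4L)
    sq <- makeUteSequence(cfg)
    model <- GradientChainModel(delay = 2e-6, eddyAmp = 0.01,
                                eddyTau = 100e-6)
    fcfg <- GstfFilterConfig()
    H <- chainTransfer(model, applyGstfGrid(sq$gx, fcfg))
    corr <- correctTrajectory(sq, H, H, cfg = fcfg, filter = FALSE)
    # oracle: exact time-domain chain response of the resampled base
    # readout (integer-raster delay shift + one-pole settling integrator),
    # integrated and sampled with the shared extraction path
    wr <- resampleWaveform(sq$gx, fcfg@resampleDt, fcfg@pad)
    nd <- round(model@delay / fcfg@resampleDt)
    gDel <- c(rep(0, nd), wr@samples[seq_len(length(wr@samples) - nd)])
    tauE <- model@eddyTau[1L]
    settled <- onePoleConvOracle(gDel, fcfg@resampleDt,
                                 1 / (2 * pi * tauE))
    gTrue <- gDel - model@eddyAmp[1L] * (gDel - settled)
    nPad <- round(fcfg@pad / fcfg@resampleDt)
    core <- gTrue[(nPad + 1L):(length(gTrue) - nPad)]
    kOracle <- kFromGradientSeries(core, fcfg@resampleDt, sq$gx@t0,
                                   sq$traj@sampleTimes)
    base <- sqrt(corr@kx[, 1L]^2 + corr@ky[, 1L]^2) *
        sign(cos(corr@spokeAngles[1L]))
    expect_lt(max(abs(corr@kx[, 1L] - kOracle * cos(sq$traj@spokeAngles[1L]))),
              1e-6)
})

test_that("correction commutes with in-plane rotation for equal axis responses", {
    cfg <- quickSeqConfig(n = 32L, nSpokes = 5L)
    sq <- makeUteSequence(cfg)
    model <- GradientChainModel(delay = 1e-6, eddyAmp = 0.02,
                                eddyTau = 80e-6)
    H <- chainTransfer(model, seq(-5e6, 5e6, by = 500))
    fast <- correctTrajectory(sq, H, H, filter = FALSE)
    # rotate the base gradients manually and correct per axis
    th <- sq$traj@spokeAngles[3L]
    gxs <- initialize(sq$gx, samples = cos(th) * sq$gx@samples)
    gys <- initialize(sq$gy, samples = sin(th) * sq$gx@samples)
    kx <- kFromGradientSeries(applyGstf(gxs, H, filter = FALSE)@samples,
                              0.1e-6, 0, sq$traj@sampleTimes)
    ky <- kFromGradientSeries(applyGstf(gys, H, filter = FALSE)@samples,
                              0.1e-6, 0, sq$traj@sampleTimes)
    expect_lt(max(abs(fast@kx[, 3L] - kx)), 1e-9)
    expect_lt(max(abs(fast@ky[, 3L] - ky)), 1e-9)
})
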