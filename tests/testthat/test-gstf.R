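# Thin-slice processing: coil condensation, phase isolation,
# differentiation and least-squares transfer-function estimation.

test_that("coil condensation recovers dominant components and averages", {
    base <- exp(1i * seq(0, 4, length.out = 256L))
    ds <- manualThinSlice(function(eps, sg, co) base, nCoils = 3L)
    dc <- condenseSignals(ds, 1L)
    z <- dc@signals[1L, 1L, 1L, 1L, 1L, ]
    # rank-1 input: single component proportional to the common signal
    corr <- Mod(sum(Conj(z) * base)) / sqrt(sum(Mod(z)^2) * sum(Mod(base)^2))
    expect_equal(corr, 1, tolerance = 1e-12)
    expect_error(condenseSignals(ds, 5L), "between 1")
    expect_error(condenseSignals(manualThinSlice(function(...) rep(0i, 256L))),
                 "degenerate")

    # two orthogonal coil signals: both recovered, reconstruction exact
    s1 <- exp(2i * pi * (0:255) / 16)
    s2 <- exp(2i * pi * (0:255) / 8)
    ds2 <- manualThinSlice(function(eps, sg, co) if (co == 1L) s1 else s2,
                           nCoils = 2L)
    dc2 <- condenseSignals(ds2, 2L)
    # the span of the retained components reproduces the stacked data
    X <- rbind(s1, s2)
    C <- rbind(dc2@signals[1L, 1L, 1L, 1L, 1L, ],
               dc2@signals[1L, 1L, 1L, 2L, 1L, ])
    proj <- Conj(t(C)) %*% solve(C %*% Conj(t(C))) %*% C
    expect_lt(relErr(X %*% proj, X), 1e-10)
})

test_that("complex averaging reduces noise like 1/sqrt(N)", {
    set.seed(7)
    nAvg <- 100L; nSamp <- 512L; sdN <- 0.05
    clean <- exp(1i * 0.3 * sin(2 * pi * (0:(nSamp - 1L)) / 64))
    noisy <- function(eps, sg, co)
        clean + complex(real = rnorm(nSamp, sd = sdN),
                        imaginary = rnorm(nSamp, sd = sdN))
    ds <- manualThinSlice(noisy, nSamp = nSamp, nAvg = nAvg)
    dc <- condenseSignals(ds, 1L)
    z <- dc@signals[1L, 1L, 1L, 1L, 1L, ]
    # undo the arbitrary SVD scale/phase before measuring the residual
    alpha <- sum(Conj(clean) * z) / sum(Mod(clean)^2)
    resid <- z / alpha - clean
    measured <- sqrt(mean(c(Re(resid)^2, Im(resid)^2)))
    expect_equal(measured, sdN / sqrt(nAvg), tolerance = 0.1)
})

test_that("static off-resonance and common zeroth-order terms cancel", {
    tt <- (0:255) * 1e-5
    offres <- function(eps, sg, co) exp(1i * 2 * pi * 40 * tt)
    ph1 <- isolatePhaseComponents(condenseSignals(manualThinSlice(offres)))
    expect_lt(max(abs(ph1@firstOrder)), 1e-10)

    b0 <- 0.2 * sin(2 * pi * 50 * tt)        # polarity-signed, slice-common
    withB0 <- function(eps, sg, co) exp(1i * eps * b0)
    ph2 <- isolatePhaseComponents(condenseSignals(manualThinSlice(withB0)))
    expect_lt(max(abs(ph2@firstOrder)), 1e-10)
    expect_equal(ph2@zerothOrder[1L, ], b0 - b0[1L], tolerance = 1e-10)
})

test_that("noiseless simulated first-order phase equals the injected integral", {
    tri <- tinyTriangles(3L)
    ds <- simulateThinSlice(GradientChainModel(delay = 0, eddyAmp = numeric(0),
                                               eddyTau = numeric(0)),
                            tri, nCoils = 1L, nAverages = 1L,
                            dwell = 0.6e-6, window = 4e-3, pulseStart = 1e-3)
    ph <- isolatePhaseComponents(condenseSignals(ds))
    tRead <- ph@time
    for (i in seq_along(tri@amplitudes)) {
        w <- tri@waveforms[[i]]
        tb <- 1e-3 + (seq_along(w@samples) - 1L) * w@dt
        oracle <- GAMMA_RAD * 0.02 * pwlIntegral(tb, w@samples, tRead)
        expect_lt(max(abs(ph@firstOrder[i, ] - (oracle - oracle[1L]))), 1e-9)
    }
})

test_that("phase differentiation recovers gradients with bounded error", {
    tt <- (0:499) * 1e-5
    mk <- function(phi) new("PhaseSeries", time = tt,
                            firstOrder = matrix(phi - phi[1L], 1L),
                            zerothOrder = matrix(0, 1L, length(tt)),
                            sliceOffset = 0.02)
    g0 <- phaseToGradient(mk(rep(0, 500)))[[1L]]
    expect_true(all(g0@samples == 0))
    phiLin <- GAMMA_RAD * 0.02 * 10e-3 * tt
    gLin <- phaseToGradient(mk(phiLin))[[1L]]
    expect_lt(max(abs(gLin@samples - 10e-3)), 1e-9)
    # quadratic phase (linear ramp): central differences are exact in the
    # interior; one-sided ends are off by slope * dt / 2
    slope <- 50                                  # T/m/s ramp
    phiQ <- GAMMA_RAD * 0.02 * slope * tt^2 / 2
    gQ <- phaseToGradient(mk(phiQ))[[1L]]
    expect_lt(max(abs(gQ@samples[2:499] - slope * tt[2:499])), 1e-9)
    expect_lt(abs(gQ@samples[1L] - slope * tt[1L]) , slope * 1e-5 / 2 + 1e-9)
    expect_error(phaseToGradient(mk(phiLin), D_r = -1), "positive")
})

test_that("least-squares estimation handles exact, null and delayed inputs", {
    tri <- tinyTriangles(4L)
    window <- 4e-3; dwell <- 2e-6
    n <- round(window / dwell)
    tGrid <- (seq_len(n) - 1L) * dwell
    sampleTri <- function(w, shift = 0) {
        tb <- 0.5e-3 + shift + (seq_along(w@samples) - 1L) * w@dt
        GradientWaveform("meas", pwlEval(tb, w@samples, tGrid), dt = dwell)
    }
    measEq <- lapply(tri@waveforms, sampleTri)
    H <- estimateGstf(tri, measEq, window, pulseStart = 0.5e-3)
    expect_equal(H@df, 1 / window, tolerance = 1e-12)
    ok <- H@characterized
    expect_lt(max(Mod(H@H[ok] - 1)), 1e-9)

    meas0 <- lapply(tri@waveforms, function(w)
        GradientWaveform("meas", rep(0, n), dt = dwell))
    H0 <- estimateGstf(tri, meas0, window, pulseStart = 0.5e-3)
    expect_lt(max(Mod(H0@H[H0@characterized])), 1e-12)

    tau <- 2e-6
    measDel <- lapply(tri@waveforms, sampleTri, shift = tau)
    Hd <- estimateGstf(tri, measDel, window, pulseStart = 0.5e-3)
    sel <- Hd@characterized & abs(Hd@freq) <= 6e3 & Hd@freq != 0
    phExp <- -2 * pi * Hd@freq[sel] * tau
    expect_lt(max(abs(Arg(Hd@H[sel]) - phExp) / abs(phExp)), 0.01)
})

test_that("transfer-function comparison recovers band maxima and group delay", {
    f <- seq(-15e3, 15e3, by = 100 / 3)
    chain <- idChain()
    h <- chainTransferValues(chain, f)
    H1 <- Gstf("X", f, h)
    same <- compareGstfs(H1, H1)
    expect_true(all(same@maxMag == 0) && all(same@maxPhase == 0))
    expect_identical(same@dcDelay, 0)

    H2 <- Gstf("X", f, h * exp(-1i * 2 * pi * f * 0.06e-6))
    rep2 <- compareGstfs(H1, H2, fitBand = 2e3)
    expect_equal(rep2@dcDelay, 0.06e-6, tolerance = 1e-9 / 0.06)

    H3 <- Gstf("X", f, h * (1 + 1e-3 / Mod(h)))
    rep3 <- compareGstfs(H1, H3)
    expect_equal(unname(rep3@maxMag), rep(1e-3, 3L), tolerance = 1e-9)
    expect_lt(max(rep3@maxPhase), 1e-12)
    # nested bands are nondecreasing
    expect_true(!is.unsorted(rep2@maxMag) && !is.unsorted(rep2@maxPhase))
    expect_error(compareGstfs(H1, Gstf("X", f + 1e6, h)), "overlap")
})

test_that("zeroth-order and off-resonance injections never leak to first order", {
    tri <- tinyTriangles(3L)
    chain <- idChain()
    clean <- simulateThinSlice(chain, tri, nCoils = 1L, nAverages = 1L,
                               dwell = 1.2e-6, window = 6e-3)
    dirty <- simulateThinSlice(
        GradientChainModel(delay = 2e-6, eddyAmp = 0.01, eddyTau = 100e-6,
                           b0Amp = 5e-4, b0Tau = 200e-6),
        tri, nCoils = 1L, nAverages = 1L, offResonance = 120,
        dwell = 1.2e-6, window = 6e-3)
    p1 <- isolatePhaseComponents(condenseSignals(clean))
    p2 <- isolatePhaseComponents(condenseSignals(dirty))
    expect_lt(max(abs(p1@firstOrder - p2@firstOrder)), 1e-9)
    expect_gt(max(abs(p2@zerothOrder)), 1e-4)   # the injection is visible
    expect_lt(max(abs(p1@zerothOrder)), 1e-10)
})
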