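# kz transform, self-navigation, binning, density compensation, coil maps,
# adjoint and compressed-sensing reconstruction.

test_that("the kz transform is unitary, centered and invertible", {
    set.seed(11)
    d <- c(6L, 5L, 8L, 2L, 1L)
    y <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
    # single partition: identity
    y1 <- y[, , 1L, , , drop = FALSE]
    expect_identical(kzTransform(y1), y1)
    # round trip
    expect_lt(relErr(kzTransformForward(kzTransform(y)), y), 1e-12)
    # impulse at kz = 0 (center index) -> constant across slices
    imp <- array(0i, d)
    imp[1L, 1L, 5L, 1L, 1L] <- 1 + 0i      # center of 8 partitions
    sl <- kzTransform(imp)[1L, 1L, , 1L, 1L]
    expect_lt(max(Mod(sl - sl[1L])), 1e-12)
    expect_error(kzTransform(array(0i, c(2, 2, 2))), "expected")
})

test_that("navigator extraction is null for static data and finds breathing", {
    cfg <- quickSeqConfig(n = 64L, nSpokes = 300L, fov = 0.4, dwell = 2.2e-6)
    sq <- makeUteSequence(cfg)
    phS <- makeMotionPhantom(n = 64L, fov = 0.4, peakDisplacement = 0,
                             nCoils = 4L)
    simS <- simulateAcquisition(phS, sq$traj, cfg, nStates = 1L)
    # the first center-out sample sits exactly at k = 0, whose magnitude
    # (the total intensity) is angle-independent for a static object
    navS <- extractNavigator(simS$kspace, ReconConfig(centerSamples = 1))
    expect_lt(max(abs(navS)) / Mod(simS$kspace@y[1L, 1L, 1L, 1L, 1L]), 1e-10)
    expect_error(extractNavigator(simS$kspace,
                                  ReconConfig(centerSamples = 1e4)),
                 "exceeds")

    ph <- makeMotionPhantom(n = 64L, fov = 0.4, nCoils = 8L)
    sim <- simulateAcquisition(ph, sq$traj, cfg, nStates = 32L)
    # exact-center navigator: free of golden-angle angular leakage, its
    # dominant spectral peak sits at the breathing frequency (0.25 Hz)
    # within one frequency bin
    nav <- extractNavigator(sim$kspace, ReconConfig(centerSamples = 1))
    interval <- attr(nav, "interval")
    expect_equal(interval, 0.88683, tolerance = 1e-9)
    best <- which.max(apply(nav, 2L, sd))
    p <- Mod(fft(nav[, best]))^2
    nS <- nrow(nav)
    fAx <- (seq_len(nS) - 1L) / (nS * interval)
    sel <- fAx > 0.01 & fAx < 0.5 / interval
    fPk <- fAx[sel][which.max(p[sel])]
    expect_lt(abs(fPk - 1 / ph@period), 1 / (nS * interval) + 1e-9)
    # the default nine-sample navigator still yields a motion-dominated
    # surrogate after coil scoring and principal component analysis
    sg <- deriveSurrogate(extractNavigator(sim$kspace))
    expect_gt(abs(cor(sg@value, sim$surrogate)), 0.9)
})

test_that("surrogate derivation scores, selects, and orients coils", {
    set.seed(5)
    ns <- 200L
    tt <- (seq_len(ns) - 1L) * 0.887
    truth <- sin(pi * tt / 4)^4                 # inspiration-up motion
    expUp <- 1 - truth                          # expiration-up convention
    nav <- cbind(0.03 * rnorm(ns),              # pure-noise coil
                 expUp + 0.01 * rnorm(ns))      # respiratory coil
    attr(nav, "interval") <- 0.887
    sg <- deriveSurrogate(nav)
    expect_identical(sg@keptCoils, 2L)
    expect_gt(abs(cor(sg@value, truth)), 0.99)
    # sign convention: the plateau (end-expiration) sits at the maximum,
    # so the surrogate correlates positively with expiration-up truth
    expect_gt(cor(sg@value, expUp), 0.99)

    # two identical coils: the first component is the common signal
    nav2 <- cbind(expUp, expUp)
    attr(nav2, "interval") <- 0.887
    sg2 <- deriveSurrogate(nav2)
    expect_gt(abs(cor(sg2@value, expUp)), 1 - 1e-9)

    navBad <- cbind(rnorm(ns), rnorm(ns))
    attr(navBad, "interval") <- 0.887
    expect_error(deriveSurrogate(navBad, minScore = 0.9),
                 "no respiratory signal")
})

test_that("overlapped binning satisfies the counting rules", {
    cfg <- ReconConfig()
    v <- sin(1:100)                            # arbitrary surrogate
    ba <- binSpokes(v, cfg)
    expect_identical(lengths(ba@primary), rep(20L, 5L))
    memb <- table(unlist(ba@members))
    expect_identical(sum(lengths(ba@members)), 180L)
    expect_true(all(memb >= 1L & memb <= 2L))
    # monotonic ramp: lowest primary bin holds the 20 smallest values
    ramp <- binSpokes(seq_len(100L), cfg)
    expect_identical(ramp@primary[[1L]], 1:20)
    # outer halves of the extreme bins stay single-membership
    expect_identical(sum(table(unlist(ramp@members))[1:10] == 1L), 10L)
    expect_identical(sum(table(unlist(ramp@members))[91:100] == 1L), 10L)
    # uneven spoke count: primary counts differ by at most 1
    ba2 <- binSpokes(rnorm(101L), cfg)
    expect_lte(diff(range(lengths(ba2@primary))), 1L)
    expect_error(binSpokes(v, ReconConfig(overlap = 0.7)), "0.5")
    # no overlap: membership equals primary
    ba0 <- binSpokes(v, ReconConfig(overlap = 1e-9))
    expect_identical(ba0@primary, ba0@members)
})

test_that("density weights are a nonnegative radial ramp with center floor", {
    cfg <- quickSeqConfig(n = 64L, nSpokes = 200L,
                          tes = c(0.176e-3, 1.849e-3))
    sq <- makeUteSequence(cfg)
    W <- densityWeights(sq$traj)
    expect_true(all(is.finite(W)) && all(W >= 0))
    # uniformly sampled full spoke (echo 2): weight proportional to |k|
    # away from the center
    W2 <- densityWeights(sq$traj, echo = 2L)
    win2 <- sq$traj@echoWindows[[2L]]
    kb2 <- sqrt(sq$traj@kx[win2$start:win2$end, 1L]^2 +
                    sq$traj@ky[win2$start:win2$end, 1L]^2)
    away <- which(kb2 > 5)
    ratio <- W2[away, 1L] / kb2[away]
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
    expect_gt(W[1L, 1L], 0)                    # center floor
    # weighted PSF: sharper main lobe relative to background than unweighted
    n <- 64L
    win <- sq$traj@echoWindows[[1L]]
    smp <- win$start:win$end
    plan <- nufftPlan(sq$traj@kx[smp, ], sq$traj@ky[smp, ], cfg@fov, n)
    delta <- matrix(0i, n, n); delta[33L, 33L] <- 1 + 0i
    vals <- nufftForward(plan, delta)
    psfW <- Mod(nufftAdjoint(plan, as.vector(W) * vals))
    psfU <- Mod(nufftAdjoint(plan, vals / length(vals)))
    contrast <- function(p) p[33L, 33L] / mean(p[abs(row(p) - 33) > 5 |
                                                     abs(col(p) - 33) > 5])
    expect_gt(contrast(psfW), contrast(psfU))
})

test_that("coil maps are normalized, supported and accurate", {
    cfg <- quickSeqConfig(n = 64L, nSpokes = 400L)
    sq <- makeUteSequence(cfg)
    ph <- makeMotionPhantom(n = 64L, fov = 0.5, peakDisplacement = 0,
                            nCoils = 2L)
    sim <- simulateAcquisition(ph, sq$traj, cfg, nStates = 1L)
    y <- array(sim$kspace@y[, , 1L, , 1L], c(dim(sim$kspace@y)[1:2], 2L))
    tr <- sim$kspace@traj
    maps <- estimateCoilMaps(y, tr, 64L, supportFrac = 0.05)
    rssm <- sqrt(apply(Mod(maps@maps)^2, c(1, 2), sum))
    expect_lt(max(abs(rssm[maps@support] - 1)), 1e-6)
    expect_true(all(rssm[!maps@support] == 0))
    rss <- sqrt(apply(Mod(ph@coilSens)^2, c(1, 2), sum))
    trueMaps <- ph@coilSens / array(rss, dim(ph@coilSens))
    err <- Mod(maps@maps - trueMaps)[rep(maps@support, 2L)] /
        Mod(trueMaps)[rep(maps@support, 2L)]
    expect_lt(mean(err), 0.05)
    # a single uniform coil gives a unit map inside the support
    phU <- makeMotionPhantom(n = 64L, fov = 0.5, peakDisplacement = 0,
                             nCoils = 2L)
    phU@coilSens[] <- 1 + 0i
    simU <- simulateAcquisition(phU, sq$traj, cfg, nStates = 1L)
    yU <- array(simU$kspace@y[, , 1L, 1L, 1L], c(dim(simU$kspace@y)[1:2], 1L))
    mapsU <- estimateCoilMaps(yU, tr, 64L, supportFrac = 0.05)
    expect_lt(max(Mod(mapsU@maps[, , 1L][mapsU@support] - 1)), 1e-3)
    expect_error(estimateCoilMaps(array(0i, dim(yU)), tr, 64L), "degenerate")
})

test_that("the adjoint reconstruction localizes sources and recovers the phantom", {
    cfg <- quickSeqConfig(n = 64L, nSpokes = 664L)
    sq <- makeUteSequence(cfg)
    tr0 <- sq$traj
    win <- tr0@echoWindows[[1L]]
    smp <- win$start:win$end
    # zero data -> zero image
    ph <- makeMotionPhantom(n = 64L, fov = 0.5, peakDisplacement = 0,
                            nCoils = 2L)
    sim <- simulateAcquisition(ph, tr0, cfg, nStates = 1L)
    y <- array(sim$kspace@y[, , 1L, , 1L], c(dim(sim$kspace@y)[1:2], 2L))
    tr <- sim$kspace@traj
    maps <- estimateCoilMaps(y, tr, 64L, supportFrac = 0.05)
    z <- reconAdjoint(array(0i, dim(y)), tr, maps)
    expect_true(all(Mod(z@data) == 0))
    # delta object: image maximum at the source pixel
    delta <- matrix(0i, 64L, 64L); delta[20L, 45L] <- 1 + 0i
    vals <- nudftForward(delta, tr0@kx[smp, ], tr0@ky[smp, ], cfg@fov)
    yD <- array(vals, c(length(smp), 664L, 1L))
    mapsU <- new("CoilMaps", maps = array(1 + 0i, c(64L, 64L, 1L)),
                 support = matrix(TRUE, 64L, 64L))
    recD <- Mod(reconAdjoint(yD, tr, mapsU)@data[, , 1L, 1L])
    expect_identical(which(recD == max(recD), arr.ind = TRUE)[1, ],
                     c(row = 20L, col = 45L))
    # full phantom
    img <- Mod(reconAdjoint(y, tr, maps)@data[, , 1L, 1L])
    expect_lt(imageNrmse(img, rssReference(ph)), 0.1)
})

test_that("forward and adjoint multi-coil operators pass the dot test per bin", {
    cfg <- quickSeqConfig(n = 32L, nSpokes = 60L, fov = 0.4, dwell = 2.2e-6)
    sq <- makeUteSequence(cfg)
    ph <- makeMotionPhantom(n = 32L, fov = 0.4, nCoils = 3L)
    win <- sq$traj@echoWindows[[1L]]
    smp <- win$start:win$end
    bins <- binSpokes(sin(seq_len(60L)), ReconConfig(nBins = 3L))
    rss <- sqrt(apply(Mod(ph@coilSens)^2, c(1, 2), sum))
    maps <- ph@coilSens / array(rss, dim(ph@coilSens))
    for (b in seq_along(bins@members)) {
        sp <- bins@members[[b]]
        plan <- nufftPlan(sq$traj@kx[smp, sp], sq$traj@ky[smp, sp],
                          cfg@fov, 32L)
        fwd <- function(x) as.vector(mcForward(plan, maps, x))
        adj <- function(v) mcAdjoint(plan, maps,
                                     matrix(v, ncol = 3L))
        res <- dotProductResidual(fwd, adj, 32L, plan$M * 3L, seed = b)
        expect_lt(res, 1e-6)
    }
})

test_that("compressed sensing descends monotonically and scales homogeneously", {
    cfg <- quickSeqConfig(n = 32L, nSpokes = 120L, fov = 0.4, dwell = 2.2e-6)
    sq <- makeUteSequence(cfg)
    ph <- makeMotionPhantom(n = 32L, fov = 0.4, nCoils = 3L)
    sim <- simulateAcquisition(ph, sq$traj, cfg, nStates = 16L)
    y <- array(sim$kspace@y[, , 1L, , 1L], c(dim(sim$kspace@y)[1:2], 3L))
    tr <- sim$kspace@traj
    maps <- estimateCoilMaps(y, tr, 32L, supportFrac = 0.05)
    bins <- binSpokes(sim$surrogate, ReconConfig(nBins = 2L))
    rcfg <- ReconConfig(nBins = 2L, nIter = 6L)
    cs <- reconCs(y, tr, maps, bins, rcfg)
    expect_true(all(diff(cs$objective) <= 1e-9 * cs$objective[1L]))
    expect_true(all(is.finite(cs$objective)))
    # zero data with lambda 0: minimizer stays at zero
    cs0 <- reconCs(array(0i, dim(y)), tr, maps, bins,
                   ReconConfig(nBins = 2L, nIter = 3L, lambdaFrac = 0))
    expect_true(all(Mod(cs0$image@data) == 0))
    # doubling the data doubles lambda and the solution exactly
    cs2 <- reconCs(2 * y, tr, maps, bins, rcfg)
    expect_equal(cs2$lambda, 2 * cs$lambda, tolerance = 1e-12)
    expect_lt(max(Mod(cs2$image@data - 2 * cs$image@data)) /
                  max(Mod(cs2$image@data)), 1e-6)
})
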