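# Breathing digital phantom and multi-coil stack-of-stars forward model.

#' Construct a breathing digital phantom
#'
#' Deterministic (per seed) torso phantom: body ellipse of unit intensity,
#' two low-intensity lungs, a liver dome whose diaphragm boundary is
#' displaced by peakDisplacement * s(t) with s the periodic respiratory
#' surrogate in [0, 1] (displacement 0 at s = 0), and a bright
#' high-contrast disk for edge-sharpness metrics. Smooth complex coil
#' profiles (Gaussian lobes around the body plus a constant floor) are
#' attached.
#'
#' @param n image grid size (even).
#' @param fov field of view (m).
#' @param period respiratory period (s).
#' @param peakDisplacement peak diaphragm displacement (m).
#' @param nCoils number of receive channels.
#' @param seed RNG seed (slight per-coil randomization).
#' @return a \linkS4class{MotionPhantom}.
#' @export
makeMotionPhantom <- function(n = 128L, fov = 0.4, period = 4,
                              peakDisplacement = 0.015, nCoils = 8L,
                              seed = 1L) {
    stopifnotPositive(n = n, fov = fov, period = period, nCoils = nCoils)
    if (peakDisplacement < 0) stop("peakDisplacement must be >= 0")
    set.seed(seed)
    x <- ((seq_len(n) - 1) - n / 2) * fov / n
    xg <- matrix(x, n, n)
    yg <- t(xg)
    ang <- 2 * pi * (seq_len(nCoils) - 1) / nCoils +
        0.1 * runif(nCoils)
    sens <- array(0i, c(n, n, nCoils))
    for (c in seq_len(nCoils)) {
        # smooth low-order polynomial profile along the coil direction,
        # nonzero over the whole field of view
        u <- (xg * cos(ang[c]) + yg * sin(ang[c])) / fov     # [-0.5, 0.5]
        v <- (-xg * sin(ang[c]) + yg * cos(ang[c])) / fov
        mag <- 0.65 + 0.5 * u + 0.25 * (u^2 - v^2) * runif(1)
        ph <- 2 * pi * (0.1 * runif(1) * u + 0.05 * runif(1) * v) +
            2 * pi * runif(1)
        sens[, , c] <- mag * exp(1i * ph)
    }
    new("MotionPhantom", n = as.numeric(n), fov = fov, period = period,
        peakDisplacement = peakDisplacement, coilSens = sens,
        seed = as.numeric(seed))
}

#' Respiratory surrogate of the phantom
#'
#' s(t) = sin(pi t / period)^4: periodic in [0, 1] with a long
#' end-expiration plateau near 0, the typical free-breathing shape.
#'
#' @param phantom a \linkS4class{MotionPhantom}.
#' @param t times (s).
#' @return surrogate values in [0, 1].
#' @export
phantomSurrogate <- function(phantom, t) {
    sin(pi * t / phantom@period)^4
}

#' Render the phantom at a motion state
#'
#' Regenerates the analytic geometry at surrogate value s (the diaphragm
#' boundary sits \code{peakDisplacement * s} above its end-expiration
#' position), rasterized with 2x supersampling.
#'
#' @param phantom a \linkS4class{MotionPhantom}.
#' @param s surrogate value in [0, 1].
#' @return real n x n intensity matrix.
#' @export
phantomFrame <- function(phantom, s) {
    if (!is.finite(s) || s < 0 || s > 1)
        stop("motion state s must be in [0, 1]")
    n <- as.integer(phantom@n)
    fov <- phantom@fov
    ss <- 2L                              # supersampling factor
    m <- n * ss
    x <- ((seq_len(m) - 1) - m / 2) * fov / m
    xg <- matrix(x, m, m)
    yg <- t(xg)
    ell <- function(cx, cy, rx, ry) {
        ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
    }
    img <- matrix(0, m, m)
    body <- ell(0, 0, 0.42 * fov, 0.30 * fov)
    img[body] <- 1.0
    lungL <- ell(-0.15 * fov, 0.05 * fov, 0.11 * fov, 0.15 * fov) & body
    lungR <- ell(0.15 * fov, 0.05 * fov, 0.11 * fov, 0.15 * fov) & body
    img[lungL] <- 0.15
    img[lungR] <- 0.15
    # liver dome: fills the right lung below the diaphragm boundary, which
    # moves up (into the lung) with s
    yDia <- -0.04 * fov + phantom@peakDisplacement * s
    img[lungR & (yg <= yDia)] <- 0.95
    disk <- ell(-0.22 * fov, -0.16 * fov, 0.045 * fov, 0.045 * fov)
    img[disk] <- 1.8
    # average ss x ss blocks back to the n x n grid
    dim(img) <- c(ss, n, ss, n)
    colMeans(aperm(img, c(1, 3, 2, 4)), dims = 2L)
}

# Unitary centered forward DFT along a vector (used for the kz dimension).
kzForwardVector <- function(x) {
    n <- length(x)
    fftshift1(stats::fft(ifftshift1(x))) / sqrt(n)
}

#' Simulate a multi-coil stack-of-stars acquisition of the phantom
#'
#' For each spoke angle (acquired as one block of all kz partitions, so the
#' acquisition clock advances trMotion * nKz per angle) the phantom is
#' rendered at the motion state of the block time, multiplied by each coil
#' profile and sampled at the spoke's k-space positions with a type-2
#' non-uniform Fourier transform (gridding NUFFT, or exact direct summation
#' for small grids). The kz dimension uses a separable slab profile. The
#' sampling positions may be taken from a distorted "true" trajectory while
#' the returned container references the nominal one.
#'
#' @param phantom a \linkS4class{MotionPhantom}.
#' @param traj nominal \linkS4class{Trajectory} (bookkeeping reference).
#' @param seq a \linkS4class{SequenceConfig} (timing; its trMotion and nKz
#'   set the motion sampling interval).
#' @param noiseSd complex noise SD per sample.
#' @param seed RNG seed.
#' @param echo echo window index to sample.
#' @param trueTraj optional \linkS4class{Trajectory} holding the physically
#'   realized sampling positions (defaults to \code{traj}).
#' @param nKz number of simulated kz partitions (the slab profile length;
#'   can be smaller than seq's partition count, which governs timing).
#' @param nStates number of quantized motion states per period.
#' @param method "nufft" (gridding) or "direct" (exact summation oracle).
#' @return list with \code{kspace} (\linkS4class{AcquisitionKSpace}),
#'   \code{surrogate} (true surrogate per spoke) and \code{states}
#'   (quantized state index per spoke).
#' @export
simulateAcquisition <- function(phantom, traj, seq, noiseSd = 0, seed = 1L,
                                echo = 1L, trueTraj = traj, nKz = 1L,
                                nStates = 32L,
                                method = c("nufft", "direct")) {
    method <- match.arg(method)
    set.seed(seed)
    n <- as.integer(phantom@n)
    win <- traj@echoWindows[[echo]]
    smp <- win$start:win$end
    nSamp <- length(smp)
    nSpokes <- length(traj@spokeAngles)
    nCoils <- dim(phantom@coilSens)[3L]
    interval <- motionSamplingInterval(seq)
    blockT <- (seq_len(nSpokes) - 1L) * interval
    times <- outer(blockT, (seq_len(nKz) - 1L) * seq@trMotion, "+")
    sTrue <- phantomSurrogate(phantom, blockT)
    state <- pmin(nStates - 1L, pmax(0L, round(sTrue * (nStates - 1L))))
    # slab profile along z and its centered unitary spectrum
    env <- if (nKz == 1L) 1 else {
        z <- (seq_len(nKz) - 1 - floor(nKz / 2)) / nKz
        0.2 + 0.8 * cos(pi * z)^2
    }
    fz <- if (nKz == 1L) 1 else kzForwardVector(env + 0i)
    kmax <- n / (2 * phantom@fov)
    y <- array(0i, c(nSamp, nSpokes, nKz, nCoils, 1L))
    for (st in sort(unique(state))) {
        sp <- which(state == st)
        frame <- phantomFrame(phantom,
                              if (nStates > 1L) st / (nStates - 1L) else 0)
        kx <- trueTraj@kx[smp, sp, drop = FALSE]
        ky <- trueTraj@ky[smp, sp, drop = FALSE]
        if (max(abs(c(kx, ky))) > kmax * (1 + 1e-9))
            warning("trajectory exceeds the phantom grid Nyquist band")
        plan <- if (method == "nufft")
            nufftPlan(kx, ky, phantom@fov, n) else NULL
        for (co in seq_len(nCoils)) {
            img <- frame * phantom@coilSens[, , co]
            vals <- if (method == "nufft") nufftForward(plan, img)
                    else nudftForward(img, kx, ky, phantom@fov)
            vm <- matrix(vals, nSamp, length(sp))
            for (p in seq_len(nKz))
                y[, sp, p, co, 1L] <- vm * fz[p]
        }
    }
    if (noiseSd > 0)
        y <- y + array(complex(real = rnorm(length(y), sd = noiseSd),
                               imaginary = rnorm(length(y), sd = noiseSd)),
                       dim(y))
    subTraj <- initialize(traj,
                          sampleTimes = traj@sampleTimes[smp],
                          kx = traj@kx[smp, , drop = FALSE],
                          ky = traj@ky[smp, , drop = FALSE],
                          kzIndex = as.integer(seq_len(nKz) - 1L - floor(nKz / 2)),
                          echoWindows = list(list(start = 1L, end = nSamp,
                                                  halfSpoke = win$halfSpoke)))
    ks <- new("AcquisitionKSpace", y = y, times = times,
              dwell = traj@sampleTimes[2L] - traj@sampleTimes[1L],
              traj = subTraj)
    list(kspace = ks, surrogate = sTrue, states = state)
}
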