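# Thin-slice processing chain: coil compression and averaging, phase
# isolation, phase -> gradient differentiation, least-squares GSTF
# estimation, and GSTF comparison.

#' Condense thin-slice signals: coil compression and complex averaging
#'
#' Compresses the coil dimension onto the dominant singular components
#' (SVD across coil channels of the full stacked data), phase-aligns every
#' average by zeroing the phase of its first sample, and combines averages
#' by the complex mean. The first retained component carries the largest
#' singular value.
#'
#' @param dataset a \linkS4class{ThinSliceDataset}.
#' @param nKeep number of singular components to retain (>= 1, <= coils).
#' @return a \linkS4class{ThinSliceDataset} with coil dimension nKeep and a
#'   single (averaged) repetition.
#' @export
condenseSignals <- function(dataset, nKeep = 1L) {
    sig <- dataset@signals
    d <- dim(sig)
    nCoils <- d[4L]
    if (nKeep < 1L || nKeep > nCoils)
        stop("nKeep must be between 1 and the number of coils")
    if (all(Mod(sig) == 0))
        stop("degenerate input: all-zero signals")
    # coils to the front, everything else stacked as columns
    X <- aperm(sig, c(4L, 1L, 2L, 3L, 5L, 6L))
    dim(X) <- c(nCoils, prod(d[-4L]))
    A <- X %*% Conj(t(X))                 # nCoils x nCoils, Hermitian
    eig <- eigen(A, symmetric = TRUE)
    U <- eig$vectors[, seq_len(nKeep), drop = FALSE]
    Xc <- Conj(t(U)) %*% X                # nKeep x M
    dim(Xc) <- c(nKeep, d[1L], d[2L], d[3L], d[5L], d[6L])
    Xc <- aperm(Xc, c(2L, 3L, 4L, 1L, 5L, 6L))
    # phase-align each average at its first sample, then complex-average
    first <- Xc[, , , , , 1L, drop = FALSE]
    align <- exp(-1i * Arg(first))
    align[Mod(first) == 0] <- 1 + 0i
    Xc <- Xc * as.vector(align)           # broadcast over the sample dim
    out <- array(0i, c(d[1L], 2L, 2L, nKeep, 1L, d[6L]))
    for (a in seq_len(d[5L]))
        out <- out + Xc[, , , , a, , drop = FALSE]
    out <- out / d[5L]
    initialize(dataset, signals = out)
}

#' Isolate first- and zeroth-order phase components
#'
#' For each triangle amplitude: unwraps the phase of each (polarity, slice)
#' series after first-sample alignment, then forms the half-difference over
#' polarity (removing static off-resonance and concomitant terms), the
#' half-difference over slices (the first-order, trajectory-relevant phase
#' over the lever arm D_r per slice) and the half-sum over slices (the
#' zeroth-order, spatially uniform phase, returned but not used for
#' trajectory correction).
#'
#' @param dataset a condensed \linkS4class{ThinSliceDataset} (the dominant
#'   coil component is used if several remain).
#' @return a \linkS4class{PhaseSeries}.
#' @export
isolatePhaseComponents <- function(dataset) {
    sig <- dataset@signals
    d <- dim(sig)
    nAmp <- d[1L]; nSamp <- d[6L]
    firstOrder <- matrix(0, nAmp, nSamp)
    zerothOrder <- matrix(0, nAmp, nSamp)
    for (i in seq_len(nAmp)) {
        ph <- array(0, c(2L, 2L, nSamp))
        for (p in 1:2) for (s in 1:2) {
            z <- sig[i, p, s, 1L, 1L, ]
            phi <- unwrapPhase(Arg(z),
                               warn_label = sprintf("amplitude %d", i))
            ph[p, s, ] <- phi - phi[1L]
        }
        polDiff <- (ph[1L, , ] - ph[2L, , ]) / 2    # [slice, sample]
        firstOrder[i, ] <- (polDiff[1L, ] - polDiff[2L, ]) / 2
        zerothOrder[i, ] <- (polDiff[1L, ] + polDiff[2L, ]) / 2
    }
    new("PhaseSeries",
        time = (seq_len(nSamp) - 1L) * dataset@dwell,
        firstOrder = firstOrder, zerothOrder = zerothOrder,
        sliceOffset = dataset@sliceOffset)
}

#' Convert a first-order phase series to measured gradient waveforms
#'
#' g(t) = (1 / (gamma * D_r)) d phi / dt, by central finite differences
#' (one-sided at the ends), per triangle amplitude.
#'
#' @param phi a \linkS4class{PhaseSeries}.
#' @param D_r lever arm (m); defaults to the recorded slice offset.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return list of \linkS4class{GradientWaveform}, one per amplitude.
#' @export
phaseToGradient <- function(phi, D_r = phi@sliceOffset, gamma = GAMMA_RAD) {
    if (!is.finite(D_r) || D_r <= 0) stop("D_r must be positive")
    dt <- phi@time[2L] - phi@time[1L]
    lapply(seq_len(nrow(phi@firstOrder)), function(i) {
        p <- phi@firstOrder[i, ]
        n <- length(p)
        dp <- numeric(n)
        dp[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / (2 * dt)
        dp[1L] <- (p[2L] - p[1L]) / dt
        dp[n] <- (p[n] - p[n - 1L]) / dt
        GradientWaveform("meas", dp / (gamma * D_r), dt = dt, t0 = 0)
    })
}

#' Least-squares GSTF estimation from nominal/measured waveform pairs
#'
#' H(f) = sum_i Conj(Gnom_i(f)) Gmeas_i(f) / sum_i |Gnom_i(f)|^2 over the
#' analysis window, with Gnom_i and Gmeas_i the discrete Fourier transforms
#' of the i-th nominal triangle (placed at \code{pulseStart}) and measured
#' waveform. Frequencies where the summed nominal energy vanishes are
#' flagged as gaps (H = NA, characterized FALSE) rather than divided by
#' zero; the band above 15 kHz is flagged uncharacterized.
#'
#' @param nominal a \linkS4class{TriangleSet}.
#' @param measured list of \linkS4class{GradientWaveform} (one per
#'   triangle) on a common raster covering the analysis window.
#' @param window analysis window duration (s); the spectral resolution of
#'   the result is df = 1/window.
#' @param pulseStart triangle start time within the window (s).
#' @return a \linkS4class{Gstf} on a DC-centered grid up to Nyquist.
#' @export
estimateGstf <- function(nominal, measured, window = 30e-3,
                         pulseStart = 0) {
    nTri <- length(nominal@amplitudes)
    if (length(measured) != nTri)
        stop("one measured waveform per nominal triangle required")
    dt <- measured[[1L]]@dt
    n <- round(window / dt)
    if (abs(n * dt - window) > 1e-9 * window)
        warning("window is not an integer number of rasters; df = 1/(n*dt)")
    tGrid <- (seq_len(n) - 1L) * dt
    num <- complex(n)
    den <- numeric(n)
    for (i in seq_len(nTri)) {
        w <- nominal@waveforms[[i]]
        gn <- pwlEval(pulseStart + w@t0 + (seq_along(w@samples) - 1L) * w@dt,
                      w@samples, tGrid)
        gm <- measured[[i]]@samples
        if (length(gm) < n)
            stop("measured waveform shorter than the analysis window")
        gm <- gm[seq_len(n)]
        Gn <- stats::fft(gn)
        Gm <- stats::fft(gm)
        num <- num + Conj(Gn) * Gm
        den <- den + Mod(Gn)^2
    }
    H <- complex(n)
    gap <- den <= .Machine$double.eps * max(den)
    H[!gap] <- num[!gap] / den[!gap]
    H[gap] <- NA_complex_
    freq <- fftFreqCentered(n, dt)
    Hc <- fftshift1(H)
    gapC <- fftshift1(gap)
    Gstf("estimated", freq, Hc, df = 1 / (n * dt),
         characterized = !gapC & abs(freq) <= 15e3)
}

#' Compare two GSTFs: band maxima and DC group-delay difference
#'
#' Reports the per-band maxima of |H1 - H2| and of the (wrapped) phase
#' difference over nested bands, and the DC group-delay difference
#' Delta tau = slope / (2 pi) of a weighted least-squares line (weights
#' |H1|^2) fitted to arg(H1 * Conj(H2)) over |f| <= fitBand.
#'
#' @param H1,H2 \linkS4class{Gstf} objects; H2 is resampled onto H1's grid
#'   if the grids differ (error if they do not overlap).
#' @param fitBand frequency band for the group-delay fit (Hz).
#' @param bands band edges for the difference maxima (Hz).
#' @return a \linkS4class{RepeatabilityReport}.
#' @export
compareGstfs <- function(H1, H2, fitBand = 2e3,
                         bands = c(2e3, 6e3, 15e3)) {
    f <- H1@freq
    if (!isTRUE(all.equal(H1@freq, H2@freq))) {
        if (max(H2@freq) < min(f) || min(H2@freq) > max(f))
            stop("frequency grids do not overlap")
        h2 <- complex(real = stats::approx(H2@freq, Re(H2@H), xout = f,
                                           ties = "ordered")$y,
                      imaginary = stats::approx(H2@freq, Im(H2@H), xout = f,
                                                ties = "ordered")$y)
    } else h2 <- H2@H
    h1 <- H1@H
    ok <- is.finite(Re(h1)) & is.finite(Re(h2))
    dphi <- Arg(h1 * Conj(h2))
    maxMag <- maxPhase <- numeric(length(bands))
    for (b in seq_along(bands)) {
        sel <- ok & abs(f) <= bands[b]
        maxMag[b] <- if (any(sel)) max(Mod(h1 - h2)[sel]) else 0
        maxPhase[b] <- if (any(sel)) max(abs(dphi)[sel]) else 0
    }
    sel <- ok & abs(f) <= fitBand
    wts <- Mod(h1[sel])^2
    fb <- f[sel]; yb <- dphi[sel]
    fm <- sum(wts * fb) / sum(wts)
    ym <- sum(wts * yb) / sum(wts)
    slope <- sum(wts * (fb - fm) * (yb - ym)) / sum(wts * (fb - fm)^2)
    new("RepeatabilityReport", bands = bands, maxMag = cummax(maxMag),
        maxPhase = cummax(maxPhase), dcDelay = slope / (2 * pi))
}
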