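# Nominal gradient waveforms: triangular test pulses, the multi-echo UTE
# stack-of-stars readout, resampling, and gradient -> k-space integration.

#' Generate a family of triangular test gradients
#'
#' Symmetric triangles ramped up and down at the maximum slew rate, with
#' peaks uniformly spaced over [ampMin, ampMax]. The ramp duration is
#' quantized up to the raster so the discrete slew never exceeds the limit
#' and the first and last samples are exactly zero.
#'
#' @param nAmplitudes number of triangles (>= 2).
#' @param ampMin,ampMax smallest and largest peak amplitude (T/m).
#' @param slew maximum slew rate (T/m/s).
#' @param dt raster time (s).
#' @return a \linkS4class{TriangleSet}.
#' @examples
#' tri <- makeTriangleSet(21, 4e-3, 15e-3, 65, 6.4e-6)
#' diff(amplitudes(tri))[1] * 1e3  # 0.55 mT/m amplitude step
#' @export
makeTriangleSet <- function(nAmplitudes, ampMin, ampMax, slew, dt) {
    if (nAmplitudes < 2)
        stop("nAmplitudes must be >= 2")
    if (!is.finite(ampMin) || !is.finite(ampMax) || ampMin <= 0 ||
        ampMax <= ampMin)
        stop("invalid amplitude bounds: need 0 < ampMin < ampMax")
    stopifnotPositive(slew = slew, dt = dt)
    amps <- seq(ampMin, ampMax, length.out = nAmplitudes)
    waveforms <- lapply(amps, function(A) {
        nUp <- ceiling(A / slew / dt)
        up <- A * seq(0L, nUp) / nUp
        GradientWaveform("test", c(up, rev(up)[-1L]), dt = dt, t0 = 0)
    })
    new("TriangleSet", waveforms = waveforms, amplitudes = amps, slew = slew)
}

#' Resample a gradient waveform onto a new raster with zero padding
#'
#' Linear interpolation onto the new raster; \code{pad} seconds of exact
#' zeros are appended on both sides, so the total duration is the original
#' plus 2 * pad.
#'
#' @param w a \linkS4class{GradientWaveform}.
#' @param dtNew new raster time (s).
#' @param pad zero-padding duration on each side (s).
#' @return a \linkS4class{GradientWaveform}.
#' @export
resampleWaveform <- function(w, dtNew, pad = 0) {
    if (!is(w, "GradientWaveform") || length(w@samples) == 0L)
        stop("empty waveform")
    stopifnotPositive(dtNew = dtNew)
    if (pad < 0) stop("pad must be >= 0")
    if (dtNew == w@dt && pad == 0) return(w)
    nPad <- round(pad / dtNew)
    dur <- (length(w@samples) - 1L) * w@dt
    tIn <- seq(0, dur, by = w@dt)
    tCore <- seq(0, dur + dtNew / 2, by = dtNew)
    tCore <- tCore[tCore <= dur + 1e-12 * dtNew]
    core <- stats::approx(tIn, w@samples, xout = pmin(tCore, dur),
                          rule = 2, ties = "ordered")$y
    GradientWaveform(w@axis, c(rep(0, nPad), core, rep(0, nPad)),
                     dt = dtNew, t0 = w@t0 - nPad * dtNew)
}

#' Integrate gradient waveforms to a k-space trajectory
#'
#' k(t) = gammaBar * integral of g from tRef to t (trapezoidal rule on the
#' raster), applied per axis.
#'
#' @param gx,gy \linkS4class{GradientWaveform}s sharing raster and start.
#' @param gammaBar gyromagnetic ratio / 2 pi (Hz/T).
#' @param tRef reference (excitation) time within the waveform span (s).
#' @return a single-spoke \linkS4class{Trajectory} whose sample times are
#'   the waveform raster.
#' @export
integrateToK <- function(gx, gy, gammaBar = GAMMA_BAR, tRef = gx@t0) {
    if (abs(gx@dt - gy@dt) > 1e-15 || abs(gx@t0 - gy@t0) > 1e-15 ||
        length(gx@samples) != length(gy@samples))
        stop("gx and gy must share raster, start time and length")
    tt <- waveTimes(gx)
    if (tRef < tt[1L] - 1e-12 || tRef > tt[length(tt)] + 1e-12)
        stop("tRef must lie within the waveform span")
    kx <- gammaBar * cumtrapz(gx@samples, gx@dt)
    ky <- gammaBar * cumtrapz(gy@samples, gy@dt)
    kx0 <- stats::approx(tt, kx, xout = tRef, rule = 2, ties = "ordered")$y
    ky0 <- stats::approx(tt, ky, xout = tRef, rule = 2, ties = "ordered")$y
    new("Trajectory", spokeAngles = 0,
        sampleTimes = tt, kx = cbind(kx - kx0), ky = cbind(ky - ky0),
        kzIndex = 0L,
        echoWindows = list(list(start = 1L, end = length(tt),
                                halfSpoke = FALSE)),
        fov = NA_real_, matrixSize = NA_real_)
}

# k values at arbitrary sample times from a raster gradient series:
# trapezoidal cumulative integral on the raster, then linear interpolation.
# Used identically for nominal and corrected gradients so that an identity
# transfer function is an exact no-op on the extracted positions.
kFromGradientSeries <- function(g, dt, t0, sampleTimes,
                                gammaBar = GAMMA_BAR, tRef = 0) {
    k <- gammaBar * cumtrapz(g, dt)
    tt <- t0 + (seq_along(g) - 1L) * dt
    k0 <- stats::approx(tt, k, xout = tRef, rule = 2, ties = "ordered")$y
    stats::approx(tt, k - k0, xout = sampleTimes, rule = 2,
                  ties = "ordered")$y
}

# Piecewise-linear breakpoints of the base (spoke at azimuth 0) readout
# gradient for a multi-echo UTE train: center-out half spoke sampled during
# ramp-up for TE1, then bipolar full-spoke gradient echoes. Breakpoint
# times are snapped to the waveform raster so the sampled series represents
# the waveform exactly. Returns breakpoints, per-echo sample times/windows
# and achieved TEs.
uteBaseReadout <- function(config, wfDt = 0.1e-6) {
    os <- config@readoutOversampling
    m <- config@matrixSize
    dwell <- config@dwell
    dk <- 1 / (os * config@fov)
    G <- dk / (GAMMA_BAR * dwell)
    if (G > config@maxGrad * (1 + 1e-9))
        stop(sprintf(paste0("infeasible sequence: readout gradient ",
                            "%.3g mT/m exceeds the %.3g mT/m limit"),
                     G * 1e3, config@maxGrad * 1e3))
    snap <- function(t) round(t / wfDt) * wfDt
    Tr <- snap(ceiling(G / config@maxSlew / wfDt) * wfDt) # ramp not steeper
    rho <- Tr / dwell                             # ramp duration in dwells
    te1 <- snap(config@tes[1L])
    # samples (dwell units) until the half spoke reaches kmax: K + rho/2
    # once the plateau is reached, sqrt(2 rho K) while still on the ramp
    K <- round(os * m / 2)
    jEnd <- if (K >= rho / 2) K + rho / 2 else sqrt(2 * rho * K)
    n1 <- floor(jEnd) + 1L
    t1 <- te1 + (seq_len(n1) - 1L) * dwell        # TE1 window sample times
    nEcho <- length(config@tes)
    Trev <- snap(ceiling(2 * G / config@maxSlew / wfDt) * wfDt) # reversal
    bp_t <- c(0, te1, te1 + Tr)
    bp_g <- c(0, 0, G)
    times <- list(t1)
    windows <- list(list(halfSpoke = TRUE))
    achieved <- te1
    gCur <- G
    if (nEcho >= 2L) {
        nFull <- round(os * m)
        tCur <- snap(t1[n1] + dwell)              # end of +G plateau (min)
        for (e in 2:nEcho) {
            # k at the plateau end, then crossing time after the reversal;
            # an extra plateau of delta shifts the crossing by 2 * delta.
            k0 <- GAMMA_BAR * pwlIntegral(c(bp_t, tCur), c(bp_g, gCur), tCur)
            cross0 <- tCur + Trev + k0 / (GAMMA_BAR * gCur)
            delta <- snap(max(0, (config@tes[e] - cross0) / 2))
            tp <- tCur + delta
            bp_t <- c(bp_t, tp, tp + Trev)
            bp_g <- c(bp_g, gCur, -gCur)
            gCur <- -gCur
            kAfter <- GAMMA_BAR * pwlIntegral(bp_t, bp_g, tp + Trev)
            cross <- tp + Trev - kAfter / (GAMMA_BAR * gCur)
            tw <- cross + (seq_len(nFull) - round(nFull / 2) - 1L) * dwell
            times[[e]] <- tw
            windows[[e]] <- list(halfSpoke = FALSE)
            achieved <- c(achieved, cross)
            tCur <- snap(tw[nFull] + dwell)
        }
    }
    tEnd <- snap(max(unlist(times)) + 2 * dwell)
    bp_t <- c(bp_t, tEnd, tEnd + abs(gCur) / config@maxSlew)
    bp_g <- c(bp_g, gCur, 0)
    bp_t[length(bp_t)] <- snap(bp_t[length(bp_t)])
    list(bp_t = bp_t, bp_g = bp_g, times = times, windows = windows,
         achievedTEs = achieved, G = G, dk = dk)
}

#' Build the multi-echo UTE stack-of-stars readout and nominal trajectory
#'
#' Constructs the base (azimuth 0) readout gradient pair for a center-out
#' half-spoke first echo sampled during the gradient ramp-up, followed by
#' bipolar full-spoke gradient echoes, and the golden-angle-ordered nominal
#' trajectory obtained by trapezoidal integration assuming ideal gradients.
#' Configured TEs are treated as requested minima; the achieved echo times
#' (earliest feasible at the gradient and slew limits) are returned.
#'
#' @param config a \linkS4class{SequenceConfig}.
#' @param wfDt raster (s) of the returned gradient waveforms; breakpoints
#'   are snapped to this raster so the sampled series is exact.
#' @return list with elements \code{gx}, \code{gy} (base readout
#'   \linkS4class{GradientWaveform} pair), \code{traj} (nominal
#'   \linkS4class{Trajectory}), \code{achievedTEs}, \code{readoutGrad}.
#' @examples
#' seq664 <- makeUteSequence(SequenceConfig())
#' sapply(echoWindows(seq664$traj), function(w) w$end - w$start + 1L)
#' @export
makeUteSequence <- function(config, wfDt = 0.1e-6) {
    base <- uteBaseReadout(config, wfDt)
    tGrid <- seq(0, base$bp_t[length(base$bp_t)] + wfDt, by = wfDt)
    g <- pwlEval(base$bp_t, base$bp_g, tGrid)
    gx <- GradientWaveform("X", g, dt = wfDt, t0 = 0)
    gy <- GradientWaveform("Y", rep(0, length(g)), dt = wfDt, t0 = 0)
    sampleTimes <- unlist(base$times)
    kBase <- kFromGradientSeries(g, wfDt, 0, sampleTimes)
    ang <- ((seq_len(config@nSpokes) - 1L) * GOLDEN_ANGLE) %% (2 * pi)
    kx <- outer(kBase, cos(ang))
    ky <- outer(kBase, sin(ang))
    ends <- cumsum(lengths(base$times))
    starts <- c(1L, head(ends, -1L) + 1L)
    windows <- lapply(seq_along(base$times), function(e)
        list(start = starts[e], end = ends[e],
             halfSpoke = base$windows[[e]]$halfSpoke))
    traj <- new("Trajectory", spokeAngles = ang, sampleTimes = sampleTimes,
                kx = kx, ky = ky,
                kzIndex = as.integer(seq_len(config@nKz) - 1L -
                                         floor(config@nKz / 2)),
                echoWindows = windows, fov = config@fov,
                matrixSize = config@matrixSize)
    list(gx = gx, gy = gy, traj = traj, achievedTEs = base$achievedTEs,
         readoutGrad = base$G)
}

#' Motion sampling interval of a stack-of-stars acquisition
#'
#' One spoke angle is acquired as a block of all kz partitions, so the
#' respiratory surrogate is sampled every trMotion * nKz seconds.
#'
#' @param config a \linkS4class{SequenceConfig}.
#' @return interval in seconds.
#' @export
motionSamplingInterval <- function(config) {
    config@trMotion * config@nKz
}
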