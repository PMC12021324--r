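# GSTF-based gradient and trajectory correction: spectral filtering of a
# measured GSTF, frequency-domain application to nominal waveforms, and
# per-spoke k-space correction.

# Tukey (tapered cosine) window with taper fraction r, evaluated as a
# symmetric function of frequency over the represented band [-F, F] so the
# filtered spectrum stays conjugate-symmetric.
tukeyWindowFreq <- function(f, r) {
    Fmax <- max(abs(f))
    edge <- (1 - r) * Fmax
    w <- rep(1, length(f))
    roll <- abs(f) > edge
    w[roll] <- 0.5 * (1 + cos(pi * (abs(f[roll]) - edge) / (r * Fmax)))
    w
}

#' Filter a measured GSTF for trajectory correction
#'
#' Beyond +/- smoothStart the spectrum is replaced by its convolution with
#' a Gaussian kernel (SD gaussSd) along frequency, reducing measurement
#' noise while leaving the passband untouched; the whole represented band
#' is then multiplied by a Tukey window (taper fraction tukeyTaper) to
#' avoid ringing in corrected waveforms. Optionally resamples the result
#' onto a target frequency grid (linear interpolation of real and
#' imaginary parts; zero outside the represented band).
#'
#' @param H a \linkS4class{Gstf} on a uniform grid.
#' @param cfg a \linkS4class{GstfFilterConfig}.
#' @param targetFreq optional numeric grid (Hz) to resample onto.
#' @return a \linkS4class{Gstf}.
#' @export
filterGstf <- function(H, cfg = GstfFilterConfig(), targetFreq = NULL) {
    f <- H@freq
    df <- H@df
    if (df > cfg@gaussSd)
        stop(sprintf(
            "kernel undersampled: grid spacing %.3g Hz exceeds the %.3g Hz Gaussian SD",
            df, cfg@gaussSd))
    h <- H@H
    h[!is.finite(Re(h))] <- 0 + 0i      # estimation gaps carry no energy
    nk <- 2L * ceiling(5 * cfg@gaussSd / df) + 1L
    kern <- stats::dnorm(seq(-(nk %/% 2L), nk %/% 2L) * df, sd = cfg@gaussSd)
    kern <- kern / sum(kern)
    sm <- function(x) {
        # centered convolution with edge-replicated padding
        half <- nk %/% 2L
        xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
        xs <- stats::filter(xp, kern, method = "convolution", sides = 2L)
        as.numeric(xs)[(half + 1L):(half + length(x))]
    }
    hs <- complex(real = sm(Re(h)), imaginary = sm(Im(h)))
    out <- h
    outer_band <- abs(f) > cfg@smoothStart
    out[outer_band] <- hs[outer_band]
    out <- out * tukeyWindowFreq(f, cfg@tukeyTaper)
    if (!is.null(targetFreq)) {
        re <- stats::approx(f, Re(out), xout = targetFreq, yleft = 0,
                            yright = 0, ties = "ordered")$y
        im <- stats::approx(f, Im(out), xout = targetFreq, yleft = 0,
                            yright = 0, ties = "ordered")$y
        dfT <- if (length(targetFreq) > 1L)
            targetFreq[2L] - targetFreq[1L] else df
        return(Gstf(H@axis, targetFreq, complex(real = re, imaginary = im),
                    df = dfT,
                    characterized = targetFreq >= min(f) &
                        targetFreq <= max(f)))
    }
    initialize(H, H = out)
}

#' Apply a GSTF to a nominal gradient waveform
#'
#' Implements the LTI gradient-chain model: the waveform is resampled to a
#' fine raster with zero padding, Fourier transformed, multiplied by the
#' (optionally filtered and) resampled transfer function, transformed back
#' and cropped to the original time span. The transfer function is
#' symmetrized to H(-f) = Conj(H(f)) (with a warning if the violation is
#' material) so the output is real; the discarded imaginary residual is
#' asserted to be below 1e-6 of the signal norm.
#'
#' @param wNom nominal \linkS4class{GradientWaveform}.
#' @param H a \linkS4class{Gstf}.
#' @param cfg a \linkS4class{GstfFilterConfig} (resampling raster, padding
#'   and filter parameters).
#' @param filter logical; apply the Gaussian/Tukey preparation of
#'   \code{\link{filterGstf}} before multiplication (the measured-GSTF
#'   pipeline). With \code{FALSE} the transfer function is applied as
#'   given (the pure convolution of the LTI model).
#' @return corrected \linkS4class{GradientWaveform} on the fine raster.
#' @export
applyGstf <- function(wNom, H, cfg = GstfFilterConfig(), filter = TRUE) {
    if (!all(is.finite(wNom@samples))) stop("waveform must be finite")
    wr <- resampleWaveform(wNom, cfg@resampleDt, cfg@pad)
    nCrop <- length(wr@samples)
    # extend to a composite FFT length (extra zeros only deepen the pad)
    n <- stats::nextn(nCrop, c(2L, 3L, 5L))
    ws <- c(wr@samples, rep(0, n - nCrop))
    freq <- (seq_len(n) - 1L) / (n * wr@dt)
    freq[freq >= 0.5 / wr@dt] <- freq[freq >= 0.5 / wr@dt] - 1 / wr@dt
    Hsrc <- if (filter) filterGstf(H, cfg) else H
    hre <- stats::approx(Hsrc@freq, Re(Hsrc@H), xout = freq, yleft = 0,
                         yright = 0, ties = "ordered")$y
    him <- stats::approx(Hsrc@freq, Im(Hsrc@H), xout = freq, yleft = 0,
                         yright = 0, ties = "ordered")$y
    hh <- complex(real = hre, imaginary = him)
    hh[!is.finite(Re(hh))] <- 0 + 0i
    # the unpaired Nyquist bin of an even-length grid must be real
    if (n %% 2L == 0L)
        hh[n / 2 + 1L] <- Re(hh[n / 2 + 1L]) + 0i
    # indices of -f for each f on the DFT grid
    negIdx <- c(1L, rev(seq_len(n - 1L) + 1L))
    hsym <- (hh + Conj(hh[negIdx])) / 2
    asym <- sqrt(sum(Mod(hh - hsym)^2))
    if (asym > 1e-8 * max(sqrt(sum(Mod(hh)^2)), 1))
        warning("transfer function violates conjugate symmetry; symmetrized")
    out <- stats::fft(stats::fft(ws) * hsym, inverse = TRUE) / n
    imagResid <- sqrt(sum(Im(out)^2))
    if (imagResid > 1e-6 * max(sqrt(sum(Mod(out)^2)), 1e-300))
        stop("conjugate-symmetry violation: excessive imaginary residual")
    nPad <- round(cfg@pad / cfg@resampleDt)
    core <- Re(out)[(nPad + 1L):(nCrop - nPad)]
    GradientWaveform(wNom@axis, core, dt = cfg@resampleDt, t0 = wNom@t0)
}

#' Correct a stack-of-stars trajectory with measured GSTFs
#'
#' Rotates the base readout gradient into physical axes per spoke, applies
#' the per-axis GSTF, integrates to k-space and extracts the sample
#' positions at the acquisition raster within each echo window. When the X
#' and Y transfer functions are identical the correction commutes with the
#' in-plane rotation, and the base spoke is corrected once and rotated.
#'
#' @param seq output of \code{\link{makeUteSequence}} (elements gx, gy,
#'   traj), or any list with those elements.
#' @param HX,HY per-axis \linkS4class{Gstf}.
#' @param cfg a \linkS4class{GstfFilterConfig}.
#' @param gammaBar gyromagnetic ratio / 2 pi (Hz/T).
#' @param filter passed to \code{\link{applyGstf}}.
#' @return corrected \linkS4class{Trajectory}.
#' @export
correctTrajectory <- function(seq, HX, HY, cfg = GstfFilterConfig(),
                              gammaBar = GAMMA_BAR, filter = TRUE) {
    if (is.null(seq$gx) || is.null(seq$gy) || is.null(seq$traj))
        stop("seq must provide gx, gy and traj")
    traj <- seq$traj
    ang <- traj@spokeAngles
    st <- traj@sampleTimes
    sameH <- isTRUE(all.equal(HX@freq, HY@freq)) &&
        isTRUE(all.equal(HX@H, HY@H))
    if (sameH) {
        gc <- applyGstf(seq$gx, HX, cfg, filter = filter)
        kBase <- kFromGradientSeries(gc@samples, gc@dt, gc@t0, st,
                                     gammaBar = gammaBar, tRef = 0)
        # base gy is identically zero for a stack-of-stars readout;
        # rotate the corrected base spoke
        kx <- outer(kBase, cos(ang))
        ky <- outer(kBase, sin(ang))
    } else {
        kx <- matrix(0, length(st), length(ang))
        ky <- matrix(0, length(st), length(ang))
        gb <- seq$gx@samples
        gyb <- seq$gy@samples
        for (s in seq_along(ang)) {
            gxs <- initialize(seq$gx,
                              samples = cos(ang[s]) * gb - sin(ang[s]) * gyb)
            gys <- initialize(seq$gy,
                              samples = sin(ang[s]) * gb + cos(ang[s]) * gyb)
            gxc <- applyGstf(gxs, HX, cfg, filter = filter)
            gyc <- applyGstf(gys, HY, cfg, filter = filter)
            kx[, s] <- kFromGradientSeries(gxc@samples, gxc@dt, gxc@t0, st,
                                           gammaBar = gammaBar, tRef = 0)
            ky[, s] <- kFromGradientSeries(gyc@samples, gyc@dt, gyc@t0, st,
                                           gammaBar = gammaBar, tRef = 0)
        }
    }
    initialize(traj, kx = kx, ky = ky)
}
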