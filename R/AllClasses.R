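# S4 containers for the measurement -> correction -> reconstruction chain.
# Constructors (same name as the class) validate invariants; slots are not
# part of the API -- use the accessors.

setClassUnion("listOrNULL", c("list", "NULL"))

#' Uniformly sampled gradient waveform for one physical axis
#'
#' Amplitude samples in T/m on a raster of spacing \code{dt} starting at
#' \code{t0} (seconds relative to RF excitation).
#'
#' @slot axis character, physical axis label ("X", "Y", "Z" or a logical
#'   readout component label).
#' @slot t0 numeric, start time (s).
#' @slot dt numeric, raster time (s), > 0.
#' @slot samples numeric vector, gradient amplitude (T/m).
#' @export
setClass("GradientWaveform",
    representation(axis = "character", t0 = "numeric", dt = "numeric",
                   samples = "numeric"),
    validity = function(object) {
        if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
            return("dt must be a single positive number")
        if (!all(is.finite(object@samples)))
            return("samples must be finite")
        TRUE
    })

#' @rdname GradientWaveform-class
#' @param axis,t0,dt,samples see slots.
#' @export
GradientWaveform <- function(axis, samples, dt, t0 = 0) {
    new("GradientWaveform", axis = as.character(axis), t0 = t0, dt = dt,
        samples = as.numeric(samples))
}

#' Family of triangular test gradients
#'
#' One symmetric triangle per amplitude, all ramped at the maximum slew rate.
#'
#' @slot waveforms list of \linkS4class{GradientWaveform}.
#' @slot amplitudes numeric, peak amplitudes (T/m).
#' @slot slew numeric, maximum slew rate (T/m/s).
#' @export
setClass("TriangleSet",
    representation(waveforms = "list", amplitudes = "numeric",
                   slew = "numeric"),
    validity = function(object) {
        if (length(object@waveforms) != length(object@amplitudes))
            return("one waveform per amplitude required")
        for (i in seq_along(object@waveforms)) {
            w <- object@waveforms[[i]]
            if (!is(w, "GradientWaveform"))
                return("waveforms must be GradientWaveform objects")
            s <- w@samples
            if (length(s) && (s[1L] != 0 || s[length(s)] != 0))
                return("test pulses must start and end at exactly 0")
            if (abs(max(s) - object@amplitudes[i]) > 1e-12 * object@amplitudes[i])
                return("peak must equal the requested amplitude")
            if (length(s) > 1L &&
                max(abs(diff(s))) / w@dt > object@slew * (1 + 1e-9))
                return("discrete slew rate exceeds the slew limit")
        }
        TRUE
    })

#' Stack-of-stars sequence parameters
#'
#' Geometry and timing of the 3D multi-echo UTE gradient-echo acquisition.
#' \code{tr} is the sequence repetition time; \code{trMotion} is the
#' repetition time entering the motion sampling interval (the two are carried
#' independently). Units SI (m, s, T/m).
#'
#' @export
setClass("SequenceConfig",
    representation(fov = "numeric", matrixSize = "numeric",
                   nSpokes = "numeric", nKz = "numeric", tes = "numeric",
                   tr = "numeric", trMotion = "numeric", dwell = "numeric",
                   readoutOversampling = "numeric", maxGrad = "numeric",
                   maxSlew = "numeric"),
    validity = function(object) {
        pos <- c(object@fov, object@matrixSize, object@nSpokes, object@nKz,
                 object@tr, object@trMotion, object@dwell,
                 object@readoutOversampling, object@maxGrad, object@maxSlew)
        if (any(!is.finite(pos)) || any(pos <= 0))
            return("all sequence parameters must be positive and finite")
        if (any(diff(object@tes) <= 0) || any(object@tes <= 0))
            return("TEs must be positive and strictly increasing")
        TRUE
    })

#' @rdname SequenceConfig-class
#' @param fov field of view (m); \code{matrixSize} in-plane matrix;
#'   \code{nSpokes} spokes per partition; \code{nKz} kz partitions;
#'   \code{tes} echo times (s); \code{tr} repetition time (s);
#'   \code{trMotion} repetition time used for the motion sampling interval
#'   (s); \code{dwell} readout dwell time (s); \code{readoutOversampling}
#'   readout oversampling factor; \code{maxGrad} gradient amplitude limit
#'   (T/m); \code{maxSlew} slew-rate limit (T/m/s).
#' @export
SequenceConfig <- function(fov = 0.5, matrixSize = 332, nSpokes = 664,
                           nKz = 103, tes = c(0.176e-3, 1.849e-3, 3.521e-3),
                           tr = 8.29e-3, trMotion = 8.61e-3,
                           dwell = 1 / (865 * 332 * 2),
                           readoutOversampling = 2,
                           maxGrad = 15e-3, maxSlew = 65) {
    new("SequenceConfig", fov = fov, matrixSize = matrixSize,
        nSpokes = nSpokes, nKz = nKz, tes = tes, tr = tr,
        trMotion = trMotion, dwell = dwell,
        readoutOversampling = readoutOversampling, maxGrad = maxGrad,
        maxSlew = maxSlew)
}

#' Per-spoke k-space trajectory
#'
#' Transverse k-space positions (m^-1) for every (readout sample, spoke),
#' with the sample clock relative to RF excitation and the index windows of
#' each echo.
#'
#' @slot spokeAngles numeric, azimuth per spoke (rad).
#' @slot sampleTimes numeric, time of each readout sample (s), strictly
#'   increasing.
#' @slot kx,ky numeric matrices [sample, spoke] (m^-1).
#' @slot kzIndex integer, Cartesian partition indices represented.
#' @slot echoWindows list; each element \code{list(start, end, halfSpoke)}
#'   gives the sample-index range of one echo and whether it is a center-out
#'   half spoke.
#' @slot fov,matrixSize imaging geometry the trajectory was designed for.
#' @export
setClass("Trajectory",
    representation(spokeAngles = "numeric", sampleTimes = "numeric",
                   kx = "matrix", ky = "matrix", kzIndex = "integer",
                   echoWindows = "list", fov = "numeric",
                   matrixSize = "numeric"),
    validity = function(object) {
        if (!all(is.finite(object@kx)) || !all(is.finite(object@ky)))
            return("kx, ky must be finite")
        if (length(object@sampleTimes) > 1L &&
            any(diff(object@sampleTimes) <= 0))
            return("sampleTimes must be strictly increasing")
        if (nrow(object@kx) != length(object@sampleTimes) ||
            ncol(object@kx) != length(object@spokeAngles))
            return("kx dimensions must be [sample, spoke]")
        if (!identical(dim(object@kx), dim(object@ky)))
            return("kx and ky must share dimensions")
        TRUE
    })

#' First-order gradient system transfer function
#'
#' Complex transfer ratio between nominal and produced gradient on a uniform,
#' DC-centered frequency grid. \code{df} equals 1 / (analyzed duration).
#' \code{characterized} flags frequencies where the estimate is defined and
#' within the characterized band (gaps from vanishing excitation energy and
#' the noise-dominated band above 15 kHz are flagged FALSE).
#'
#' @export
setClass("Gstf",
    representation(axis = "character", freq = "numeric", H = "complex",
                   df = "numeric", characterized = "logical"),
    validity = function(object) {
        if (length(object@freq) != length(object@H))
            return("freq and H must have equal length")
        if (length(object@freq) > 1L) {
            d <- diff(object@freq)
            if (max(abs(d - d[1L])) > 1e-6 * abs(d[1L]))
                return("freq grid must be uniform")
            if (abs(d[1L] - object@df) > 1e-6 * object@df)
                return("df must equal the frequency grid spacing")
        }
        if (any(!is.finite(object@H[object@characterized])))
            return("H must be finite where characterized")
        TRUE
    })

#' @rdname Gstf-class
#' @param axis,freq,H,df,characterized see slots.
#' @export
Gstf <- function(axis, freq, H, df = if (length(freq) > 1L)
                     freq[2L] - freq[1L] else NA_real_,
                 characterized = rep(TRUE, length(freq))) {
    new("Gstf", axis = as.character(axis), freq = as.numeric(freq),
        H = as.complex(H), df = df, characterized = characterized)
}

#' Raw thin-slice measurement set
#'
#' Complex signals from two thin slices placed symmetrically about
#' isocenter under triangular test gradients of both polarities.
#'
#' @slot signals complex array [amplitude, polarity, slice, coil, average,
#'   sample]; polarity order (+, -), slice order (+D, -D).
#' @slot dwell numeric, readout dwell time (s).
#' @slot sliceOffset numeric, slice offset D_r from isocenter (m), > 0.
#' @slot sliceThickness numeric (m).
#' @slot triangles the nominal \linkS4class{TriangleSet}.
#' @slot axis character, gradient axis measured.
#' @slot pulseStart numeric, triangle start time within the readout (s).
#' @export
setClass("ThinSliceDataset",
    representation(signals = "array", dwell = "numeric",
                   sliceOffset = "numeric", sliceThickness = "numeric",
                   triangles = "TriangleSet", axis = "character",
                   pulseStart = "numeric"),
    validity = function(object) {
        d <- dim(object@signals)
        if (length(d) != 6L)
            return("signals must be [amp, polarity, slice, coil, avg, sample]")
        if (d[2L] != 2L || d[3L] != 2L)
            return("both polarities and both slices must be present")
        if (d[1L] != length(object@triangles@amplitudes))
            return("one amplitude index per triangle required")
        if (object@dwell <= 0 || object@sliceOffset <= 0)
            return("dwell and sliceOffset must be positive")
        TRUE
    })

#' Isolated phase components per triangle amplitude
#'
#' Unwrapped first-order (trajectory-relevant) and zeroth-order (spatially
#' uniform) phase time series after polarity and slice combinations. The
#' first sample of every series is 0 by convention.
#'
#' @export
setClass("PhaseSeries",
    representation(time = "numeric", firstOrder = "matrix",
                   zerothOrder = "matrix", sliceOffset = "numeric"),
    validity = function(object) {
        if (ncol(object@firstOrder) != length(object@time))
            return("firstOrder must be [amplitude, sample]")
        if (max(abs(object@firstOrder[, 1L])) > 1e-9)
            return("phase alignment convention: phase[0] must be 0")
        TRUE
    })

#' GSTF repeatability / comparison report
#'
#' Band-wise maxima of magnitude and phase differences between two transfer
#' functions, and the DC group-delay difference from a weighted linear fit
#' of the phase of H1 * Conj(H2) near DC.
#'
#' @export
setClass("RepeatabilityReport",
    representation(bands = "numeric", maxMag = "numeric",
                   maxPhase = "numeric", dcDelay = "numeric"),
    validity = function(object) {
        if (any(object@maxMag < 0) || any(object@maxPhase < 0))
            return("band maxima must be nonnegative")
        if (is.unsorted(object@maxMag) || is.unsorted(object@maxPhase))
            return("band maxima must be nested (nondecreasing with band)")
        TRUE
    })

#' Analytic LTI gradient-chain model
#'
#' H(f) = exp(-i 2 pi f delay) * (1 - sum_k alpha_k (i 2 pi f tau_k) /
#' (1 + i 2 pi f tau_k)), the standard exponential-settling
#' parameterization, plus optional zeroth-order (B0) settling terms that
#' inject spatially uniform phase proportional to the applied gradient.
#'
#' @slot delay numeric, pure time delay (s), >= 0.
#' @slot eddyAmp,eddyTau numeric vectors, settling amplitudes
#'   (dimensionless, |alpha| < 1) and time constants (s).
#' @slot b0Amp,b0Tau numeric vectors for zeroth-order terms; b0Amp in
#'   T per (T/m) of applied gradient (i.e. meters).
#' @export
setClass("GradientChainModel",
    representation(delay = "numeric", eddyAmp = "numeric",
                   eddyTau = "numeric", b0Amp = "numeric",
                   b0Tau = "numeric"),
    validity = function(object) {
        if (object@delay < 0) return("delay must be >= 0")
        if (length(object@eddyAmp) != length(object@eddyTau))
            return("eddyAmp and eddyTau must pair up")
        if (any(object@eddyTau <= 0)) return("eddy time constants must be > 0")
        if (any(abs(object@eddyAmp) >= 1)) return("|eddy amplitude| must be < 1")
        if (length(object@b0Amp) != length(object@b0Tau))
            return("b0Amp and b0Tau must pair up")
        if (any(object@b0Tau <= 0)) return("b0 time constants must be > 0")
        TRUE
    })

#' @rdname GradientChainModel-class
#' @param delay,eddyAmp,eddyTau,b0Amp,b0Tau see slots.
#' @export
GradientChainModel <- function(delay = 3e-6,
                               eddyAmp = c(0.02, 0.03, 0.01),
                               eddyTau = c(30e-6, 150e-6, 1.5e-3),
                               b0Amp = numeric(0), b0Tau = numeric(0)) {
    new("GradientChainModel", delay = delay, eddyAmp = eddyAmp,
        eddyTau = eddyTau, b0Amp = b0Amp, b0Tau = b0Tau)
}

#' GSTF correction-filter configuration
#'
#' Defaults: Gaussian smoothing (SD 0.6 kHz) applied beyond +/- 6 kHz,
#' Tukey taper fraction 0.1 over the represented band, waveform resampling
#' to a 0.1 us raster with +/- 5 ms zero padding.
#'
#' @export
setClass("GstfFilterConfig",
    representation(smoothStart = "numeric", gaussSd = "numeric",
                   tukeyTaper = "numeric", resampleDt = "numeric",
                   pad = "numeric"),
    validity = function(object) {
        v <- c(object@smoothStart, object@gaussSd, object@tukeyTaper,
               object@resampleDt, object@pad)
        if (any(!is.finite(v)) || any(v <= 0))
            return("all filter parameters must be positive")
        if (object@tukeyTaper >= 1)
            return("tukeyTaper must be in (0, 1)")
        TRUE
    })

#' @rdname GstfFilterConfig-class
#' @param smoothStart,gaussSd,tukeyTaper,resampleDt,pad see slots.
#' @export
GstfFilterConfig <- function(smoothStart = 6e3, gaussSd = 0.6e3,
                             tukeyTaper = 0.1, resampleDt = 0.1e-6,
                             pad = 5e-3) {
    new("GstfFilterConfig", smoothStart = smoothStart, gaussSd = gaussSd,
        tukeyTaper = tukeyTaper, resampleDt = resampleDt, pad = pad)
}

#' Breathing digital phantom
#'
#' Ellipse-based torso with low-intensity lungs, a diaphragm boundary
#' displaced by \code{peakDisplacement * s(t)} for a periodic surrogate
#' s(t) in [0, 1], a bright resolution disk for edge metrics, and smooth
#' complex coil sensitivity profiles.
#'
#' @export
setClass("MotionPhantom",
    representation(n = "numeric", fov = "numeric", period = "numeric",
                   peakDisplacement = "numeric", coilSens = "array",
                   seed = "numeric"),
    validity = function(object) {
        if (object@n < 8) return("grid too small")
        if (object@period <= 0) return("period must be positive")
        if (object@peakDisplacement < 0)
            return("peakDisplacement must be >= 0")
        TRUE
    })

#' Multi-coil stack-of-stars k-space
#'
#' @slot y complex array [sample, spoke, kz, coil, echo].
#' @slot times numeric matrix [spoke, kz], acquisition time of each
#'   (spoke angle, partition) block (s), nondecreasing in acquisition order.
#' @slot dwell numeric (s).
#' @slot traj the \linkS4class{Trajectory} the data were sampled on
#'   (nominal bookkeeping; the physical sampling positions may differ).
#' @export
setClass("AcquisitionKSpace",
    representation(y = "array", times = "matrix", dwell = "numeric",
                   traj = "Trajectory"),
    validity = function(object) {
        if (length(dim(object@y)) != 5L)
            return("y must be [sample, spoke, kz, coil, echo]")
        if (nrow(object@times) != dim(object@y)[2L] ||
            ncol(object@times) != dim(object@y)[3L])
            return("times must be [spoke, kz]")
        TRUE
    })

#' Respiratory surrogate per spoke angle
#' @export
setClass("RespiratorySignal",
    representation(value = "numeric", interval = "numeric",
                   component = "numeric", flipped = "logical",
                   coilScores = "numeric", keptCoils = "integer"),
    validity = function(object) {
        if (any(!is.finite(object@value))) return("values must be finite")
        TRUE
    })

#' Respiratory bin assignment
#'
#' @slot primary list (length nBins) of spoke indices forming each bin's
#'   equal-count core; \code{members} additionally includes the overlapped
#'   halves of adjacent bins.
#' @export
setClass("BinAssignment",
    representation(primary = "list", members = "list", nSpokes = "numeric"),
    validity = function(object) {
        if (length(object@primary) != length(object@members))
            return("primary and members must align")
        counts <- lengths(object@primary)
        if (max(counts) - min(counts) > 1)
            return("primary counts must be equal across bins (+/- 1)")
        memb <- table(unlist(object@members))
        if (length(memb) && (any(memb < 1) || any(memb > 2)))
            return("each spoke must be in 1 or 2 bins")
        TRUE
    })

#' Coil sensitivity maps
#' @slot maps complex array [x, y, coil]; sum of squared magnitudes is 1
#'   inside the support mask and 0 outside.
#' @export
setClass("CoilMaps",
    representation(maps = "array", support = "matrix"),
    validity = function(object) {
        rss <- sqrt(apply(Mod(object@maps)^2, c(1, 2), sum))
        if (any(abs(rss[object@support] - 1) > 1e-6))
            return("sum-of-squares must be 1 inside support")
        if (any(rss[!object@support] > 1e-12))
            return("maps must vanish outside support")
        TRUE
    })

#' Complex image series
#'
#' @slot data complex array [x, y, slice, bin].
#' @slot voxelSize numeric, voxel edge lengths (m).
#' @export
setClass("ImageSeries",
    representation(data = "array", voxelSize = "numeric"),
    validity = function(object) {
        if (length(dim(object@data)) != 4L)
            return("data must be [x, y, slice, bin]")
        if (any(!is.finite(Re(object@data))) ||
            any(!is.finite(Im(object@data))))
            return("image data must be finite")
        TRUE
    })

#' @rdname ImageSeries-class
#' @param data complex array (2-D to 4-D; trailing dimensions of length 1
#'   are added), \code{voxelSize} voxel edge lengths (m).
#' @export
ImageSeries <- function(data, voxelSize) {
    d <- dim(data)
    if (is.null(d)) stop("data must be an array")
    if (length(d) < 4L) dim(data) <- c(d, rep(1L, 4L - length(d)))
    new("ImageSeries", data = as.array(data * (1 + 0i)),
        voxelSize = voxelSize)
}

#' Reconstruction configuration
#'
#' Defaults follow the study protocol: 5 respiratory bins with 50% overlap,
#' 15 conjugate-gradient iterations, regularization weight 5% of the peak
#' adjoint reconstruction, 9 k-space-center samples for self-navigation.
#' \code{navWindow} is the moving-average width (spoke angles) for navigator
#' background subtraction; \code{epsFrac} smooths the absolute value in the
#' temporal penalty.
#'
#' @export
setClass("ReconConfig",
    representation(nBins = "numeric", overlap = "numeric", nIter = "numeric",
                   lambdaFrac = "numeric", centerSamples = "numeric",
                   epsFrac = "numeric", navWindow = "numeric"),
    validity = function(object) {
        if (object@nBins < 1) return("nBins must be >= 1")
        if (object@overlap < 0 || object@overlap >= 1)
            return("overlap must be in [0, 1)")
        if (object@nIter < 1) return("nIter must be >= 1")
        if (object@lambdaFrac < 0) return("lambdaFrac must be >= 0")
        TRUE
    })

#' @rdname ReconConfig-class
#' @param nBins,overlap,nIter,lambdaFrac,centerSamples,epsFrac,navWindow
#'   see class description.
#' @export
ReconConfig <- function(nBins = 5, overlap = 0.5, nIter = 15,
                        lambdaFrac = 0.05, centerSamples = 9,
                        epsFrac = 1e-6, navWindow = 41) {
    new("ReconConfig", nBins = nBins, overlap = overlap, nIter = nIter,
        lambdaFrac = lambdaFrac, centerSamples = centerSamples,
        epsFrac = epsFrac, navWindow = navWindow)
}

#' Line-spread-function fit result
#'
#' Gaussian fit to the derivative of an edge profile. FWHM =
#' 2 sqrt(2 ln 2) * SD, in meters.
#'
#' @export
setClass("LsfResult",
    representation(positions = "numeric", values = "numeric",
                   center = "numeric", sdv = "numeric", fwhm = "numeric",
                   residual = "numeric", undersampled = "logical"),
    validity = function(object) {
        if (object@sdv <= 0) return("SD must be positive")
        if (abs(object@fwhm - 2 * sqrt(2 * log(2)) * object@sdv) >
            1e-9 * object@fwhm)
            return("FWHM must equal 2 sqrt(2 ln 2) SD")
        TRUE
    })
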