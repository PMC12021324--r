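# Generics, accessors and show methods.

#' @rdname accessors
#' @param object a girfute S4 object.
#' @export
setGeneric("rasterTime", function(object) standardGeneric("rasterTime"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("waveSamples", function(object) standardGeneric("waveSamples"))

#' @rdname accessors
#' @export
setGeneric("waveTimes", function(object) standardGeneric("waveTimes"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("freqGrid", function(object) standardGeneric("freqGrid"))

#' @rdname accessors
#' @export
setGeneric("transferRatio", function(object) standardGeneric("transferRatio"))

#' @rdname accessors
#' @export
setGeneric("spokeAngles", function(object) standardGeneric("spokeAngles"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("echoWindows", function(object) standardGeneric("echoWindows"))

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("kSpaceData", function(object) standardGeneric("kSpaceData"))

#' Accessors for girfute classes
#'
#' \code{rasterTime}, \code{startTime}, \code{waveSamples}, \code{waveTimes}
#' expose gradient waveforms; \code{freqGrid} and \code{transferRatio} expose
#' a \linkS4class{Gstf}; \code{spokeAngles}, \code{sampleTimes},
#' \code{echoWindows} expose a \linkS4class{Trajectory}; \code{imageData} and
#' \code{voxelSize} expose an \linkS4class{ImageSeries}; \code{kSpaceData}
#' exposes the raw array of an \linkS4class{AcquisitionKSpace}.
#'
#' @name accessors
#' @aliases rasterTime startTime waveSamples waveTimes amplitudes freqGrid
#'   transferRatio spokeAngles sampleTimes echoWindows imageData voxelSize
#'   kSpaceData
NULL

setMethod("rasterTime", "GradientWaveform", function(object) object@dt)
setMethod("startTime", "GradientWaveform", function(object) object@t0)
setMethod("waveSamples", "GradientWaveform", function(object) object@samples)
setMethod("waveTimes", "GradientWaveform", function(object)
    object@t0 + (seq_along(object@samples) - 1L) * object@dt)
setMethod("amplitudes", "TriangleSet", function(object) object@amplitudes)
setMethod("freqGrid", "Gstf", function(object) object@freq)
setMethod("transferRatio", "Gstf", function(object) object@H)
setMethod("spokeAngles", "Trajectory", function(object) object@spokeAngles)
setMethod("sampleTimes", "Trajectory", function(object) object@sampleTimes)
setMethod("echoWindows", "Trajectory", function(object) object@echoWindows)
setMethod("imageData", "ImageSeries", function(object) object@data)
setMethod("voxelSize", "ImageSeries", function(object) object@voxelSize)
setMethod("kSpaceData", "AcquisitionKSpace", function(object) object@y)

setMethod("show", "GradientWaveform", function(object) {
    cat(sprintf(
        "GradientWaveform [%s]: %d samples, dt %.4g us, t0 %.4g us, peak %.3g mT/m\n",
        object@axis, length(object@samples), object@dt * 1e6,
        object@t0 * 1e6,
        if (length(object@samples)) max(abs(object@samples)) * 1e3 else 0))
})

setMethod("show", "TriangleSet", function(object) {
    a <- object@amplitudes
    cat(sprintf(
        "TriangleSet: %d triangles, %.3g-%.3g mT/m, slew %.3g mT/m/ms\n",
        length(a), min(a) * 1e3, max(a) * 1e3, object@slew))
})

setMethod("show", "Trajectory", function(object) {
    cat(sprintf(
        "Trajectory: %d spokes x %d samples, %d echo window(s), fov %.3g m, matrix %d\n",
        length(object@spokeAngles), length(object@sampleTimes),
        length(object@echoWindows), object@fov, as.integer(object@matrixSize)))
})

setMethod("show", "Gstf", function(object) {
    cat(sprintf(
        "Gstf [%s]: %d frequencies, df %.4g Hz, band +/- %.3g kHz (%d characterized)\n",
        object@axis, length(object@freq), object@df,
        max(abs(object@freq)) / 1e3, sum(object@characterized)))
})

setMethod("show", "ThinSliceDataset", function(object) {
    d <- dim(object@signals)
    cat(sprintf(
        "ThinSliceDataset [%s]: %d amplitudes x 2 polarities x 2 slices x %d coil(s) x %d average(s) x %d samples, dwell %.3g us, D %.3g mm\n",
        object@axis, d[1L], d[4L], d[5L], d[6L], object@dwell * 1e6,
        object@sliceOffset * 1e3))
})

setMethod("show", "MotionPhantom", function(object) {
    cat(sprintf(
        "MotionPhantom: %dx%d grid, fov %.3g m, period %.3g s, peak displacement %.3g mm, %d coils\n",
        as.integer(object@n), as.integer(object@n), object@fov,
        object@period, object@peakDisplacement * 1e3,
        dim(object@coilSens)[3L]))
})

setMethod("show", "AcquisitionKSpace", function(object) {
    d <- dim(object@y)
    cat(sprintf(
        "AcquisitionKSpace: %d samples x %d spokes x %d kz x %d coils x %d echo(es)\n",
        d[1L], d[2L], d[3L], d[4L], d[5L]))
})

setMethod("show", "ImageSeries", function(object) {
    d <- dim(object@data)
    cat(sprintf(
        "ImageSeries: %d x %d x %d slice(s) x %d bin(s), voxel %s mm\n",
        d[1L], d[2L], d[3L], d[4L],
        paste(sprintf("%.3g", object@voxelSize * 1e3), collapse = " x ")))
})

setMethod("show", "RepeatabilityReport", function(object) {
    cat("GSTF comparison report\n")
    for (i in seq_along(object@bands)) {
        cat(sprintf("  |f| <= %4.3g kHz: max |dH| %.3g, max |d arg H| %.3g rad\n",
                    object@bands[i] / 1e3, object@maxMag[i],
                    object@maxPhase[i]))
    }
    cat(sprintf("  DC group-delay difference: %.4g us\n",
                object@dcDelay * 1e6))
})

setMethod("show", "LsfResult", function(object) {
    cat(sprintf(
        "LSF: FWHM %.3g mm (SD %.3g mm) centered at %.3g mm%s\n",
        object@fwhm * 1e3, object@sdv * 1e3, object@center * 1e3,
        if (object@undersampled) " [undersampled edge]" else ""))
})
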