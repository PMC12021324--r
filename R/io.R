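# File I/O, configuration and logging. The package's native container for
# lossless round-trips is RDS; interchange formats are plain text: CSV for
# transfer functions, weights and objective logs, JSON for bin assignments
# and reports, YAML for configuration, NIfTI for image magnitudes.

#' Save / load girfute objects (native container)
#'
#' @param object any girfute S4 object.
#' @param path file path.
#' @return \code{readGirf} returns the stored object.
#' @export
writeGirf <- function(object, path) {
    saveRDS(object, path)
    invisible(path)
}

#' @rdname writeGirf
#' @export
readGirf <- function(path) {
    obj <- readRDS(path)
    if (isVirtualClass(class(obj)) || !isTRUE(validObject(obj, test = TRUE)))
        stop("file does not contain a valid girfute object")
    obj
}

#' Export / import a GSTF as CSV
#'
#' Columns: freq_hz, h_real, h_imag, characterized.
#'
#' @param g a \linkS4class{Gstf}; \code{path} file path; \code{axis} axis
#'   label on import.
#' @export
exportGstfCsv <- function(g, path) {
    utils::write.csv(data.frame(freq_hz = g@freq, h_real = Re(g@H),
                                h_imag = Im(g@H),
                                characterized = g@characterized),
                     path, row.names = FALSE)
    invisible(path)
}

#' @rdname exportGstfCsv
#' @export
importGstfCsv <- function(path, axis = "X") {
    d <- utils::read.csv(path)
    Gstf(axis, d$freq_hz,
         complex(real = d$h_real, imaginary = d$h_imag),
         characterized = as.logical(d$characterized))
}

#' Write a bin assignment as JSON
#'
#' @param bins a \linkS4class{BinAssignment}; \code{path} file path.
#' @export
writeBinAssignmentJson <- function(bins, path) {
    jsonlite::write_json(
        list(n_spokes = bins@nSpokes,
             primary = bins@primary,
             members = bins@members),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeBinAssignmentJson
#' @export
readBinAssignmentJson <- function(path) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    asList <- function(x) {
        if (is.matrix(x))
            lapply(seq_len(nrow(x)), function(i) as.integer(x[i, ]))
        else lapply(x, as.integer)
    }
    new("BinAssignment", primary = asList(d$primary),
        members = asList(d$members), nSpokes = as.numeric(d$n_spokes))
}

#' Write image magnitudes as NIfTI
#'
#' @param img an \linkS4class{ImageSeries}; \code{path} output file
#'   (.nii or .nii.gz).
#' @export
writeImageNifti <- function(img, path) {
    arr <- Mod(img@data)
    vox <- img@voxelSize * 1e3           # mm
    if (length(vox) < 3L) vox <- c(vox, rep(vox[1L], 3L - length(vox)))
    nii <- RNifti::asNifti(arr)
    RNifti::pixdim(nii) <- c(vox, 1)[seq_len(min(4L, length(dim(arr))))]
    RNifti::writeNifti(nii, path)
    invisible(path)
}

#' Write a per-iteration objective log as CSV
#'
#' @param objective numeric vector (entry 1 = initialization).
#' @param path file path.
#' @export
writeObjectiveCsv <- function(objective, path) {
    utils::write.csv(data.frame(iteration = seq_along(objective) - 1L,
                                objective = objective),
                     path, row.names = FALSE)
    invisible(path)
}

#' Default configuration tree
#'
#' Sections seq / chain / phantom / recon, with every default equal to the
#' study protocol value where one exists.
#'
#' @return nested list.
#' @export
girfuteConfig <- function() {
    list(
        seq = list(fov_m = 0.5, matrix = 332, spokes_per_partition = 664,
                   kz_partitions = 103,
                   tes_ms = c(0.176, 1.849, 3.521), tr_ms = 8.29,
                   tr_motion_ms = 8.61, bandwidth_hz_per_pixel = 865,
                   readout_oversampling = 2, max_grad_mt_m = 15,
                   max_slew_mt_m_ms = 65),
        gstf = list(n_amplitudes = 21, amp_min_mt_m = 4, amp_max_mt_m = 15,
                    slew_mt_m_ms = 65, slice_offset_mm = 20,
                    slice_thickness_mm = 3, window_ms = 30,
                    dwell_us = 0.6, n_averages = 100, n_coils = 8),
        chain = list(delay_us = 3, eddy_amp = c(0.02, 0.03, 0.01),
                     eddy_tau_us = c(30, 150, 1500)),
        filter = list(smooth_start_khz = 6, gauss_sd_khz = 0.6,
                      tukey_taper = 0.1, resample_dt_us = 0.1, pad_ms = 5),
        phantom = list(n = 128, fov_m = 0.4, period_s = 4,
                       peak_displacement_mm = 15, n_coils = 8),
        recon = list(n_bins = 5, overlap = 0.5, n_iter = 15,
                     lambda_frac = 0.05, center_samples = 9,
                     nav_window = 41)
    )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file; missing entries fall back to
#'   \code{\link{girfuteConfig}}.
#' @return nested list.
#' @export
readConfigYaml <- function(path) {
    user <- yaml::read_yaml(path)
    base <- girfuteConfig()
    for (sec in names(user)) {
        if (is.list(user[[sec]]) && sec %in% names(base))
            base[[sec]] <- utils::modifyList(base[[sec]], user[[sec]])
        else base[[sec]] <- user[[sec]]
    }
    base
}

#' Build typed objects from a configuration tree
#'
#' @param cfg nested list from \code{\link{girfuteConfig}} /
#'   \code{\link{readConfigYaml}}.
#' @return the corresponding S4 object.
#' @export
configSequence <- function(cfg = girfuteConfig()) {
    s <- cfg$seq
    SequenceConfig(
        fov = s$fov_m, matrixSize = s$matrix,
        nSpokes = s$spokes_per_partition, nKz = s$kz_partitions,
        tes = s$tes_ms * 1e-3, tr = s$tr_ms * 1e-3,
        trMotion = s$tr_motion_ms * 1e-3,
        dwell = 1 / (s$bandwidth_hz_per_pixel * s$matrix *
                         s$readout_oversampling),
        readoutOversampling = s$readout_oversampling,
        maxGrad = s$max_grad_mt_m * 1e-3, maxSlew = s$max_slew_mt_m_ms)
}

#' @rdname configSequence
#' @export
configChain <- function(cfg = girfuteConfig()) {
    ch <- cfg$chain
    GradientChainModel(delay = ch$delay_us * 1e-6, eddyAmp = ch$eddy_amp,
                       eddyTau = ch$eddy_tau_us * 1e-6)
}

#' @rdname configSequence
#' @export
configRecon <- function(cfg = girfuteConfig()) {
    r <- cfg$recon
    ReconConfig(nBins = r$n_bins, overlap = r$overlap, nIter = r$n_iter,
                lambdaFrac = r$lambda_frac,
                centerSamples = r$center_samples, navWindow = r$nav_window)
}

#' @rdname configSequence
#' @export
configFilter <- function(cfg = girfuteConfig()) {
    f <- cfg$filter
    GstfFilterConfig(smoothStart = f$smooth_start_khz * 1e3,
                     gaussSd = f$gauss_sd_khz * 1e3,
                     tukeyTaper = f$tukey_taper,
                     resampleDt = f$resample_dt_us * 1e-6,
                     pad = f$pad_ms * 1e-3)
}

# FNV-1a hash of a serialized object, for provenance logging.
contentHash <- function(object) {
    raw <- serialize(object, NULL)
    h <- 5381
    for (b in as.integer(raw[seq_len(min(length(raw), 65536L))]))
        h <- (h * 33 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Structured one-line stage log
#'
#' @param stage stage name; \code{...} named inputs whose content hashes
#'   are logged.
#' @export
logStage <- function(stage, ...) {
    inputs <- list(...)
    hashes <- vapply(inputs, contentHash, character(1))
    message(sprintf("[girfute] %s %s %s", format(Sys.time(), "%H:%M:%S"),
                    stage,
                    paste(sprintf("%s=%s", names(hashes), hashes),
                          collapse = " ")))
    invisible(hashes)
}
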