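# Shared numerical helpers. All quantities SI unless noted.

#' Cumulative trapezoidal integral
#'
#' @param y numeric or complex vector of samples.
#' @param dt raster spacing (s).
#' @return vector of the same length; element i is the integral from the
#'   first sample to sample i by the trapezoidal rule (first element 0).
#' @keywords internal
cumtrapz <- function(y, dt) {
    n <- length(y)
    if (n < 2L) return(rep(0, n))
    c(0, cumsum((y[-1] + y[-n]) / 2)) * dt
}

#' Unwrap a phase time series
#'
#' 1-D unwrapping along time with a pi jump threshold. Warns (once, with the
#' offending index) when consecutive raw phase differences saturate near pi,
#' which indicates the raster undersamples the phase evolution.
#'
#' @param phi numeric vector of wrapped phases (rad).
#' @param warn_label optional label included in the unwrap-failure warning.
#' @return unwrapped phase vector starting at phi[1].
#' @keywords internal
unwrapPhase <- function(phi, warn_label = NULL) {
    d <- diff(phi)
    d <- d - 2 * pi * round(d / (2 * pi))
    if (any(abs(d) > 0.95 * pi)) {
        idx <- which(abs(d) > 0.95 * pi)[1L]
        warning(sprintf(
            "possible unwrap failure%s: phase jump %.3f rad at sample %d",
            if (is.null(warn_label)) "" else paste0(" (", warn_label, ")"),
            max(abs(d)), idx))
    }
    cumsum(c(phi[1L], d))
}

# Swap halves so that DC moves between index 1 and index n/2 + 1.
fftshift1 <- function(x) {
    n <- length(x)
    c(x[(floor(n / 2) + 1L):n], x[1:floor(n / 2)])
}

ifftshift1 <- function(x) {
    n <- length(x)
    c(x[(ceiling(n / 2) + 1L):n], x[1:ceiling(n / 2)])
}

fftshift2 <- function(x) {
    n1 <- nrow(x); n2 <- ncol(x)
    x[c((floor(n1 / 2) + 1L):n1, 1:floor(n1 / 2)),
      c((floor(n2 / 2) + 1L):n2, 1:floor(n2 / 2)), drop = FALSE]
}

ifftshift2 <- function(x) {
    n1 <- nrow(x); n2 <- ncol(x)
    x[c((ceiling(n1 / 2) + 1L):n1, 1:ceiling(n1 / 2)),
      c((ceiling(n2 / 2) + 1L):n2, 1:ceiling(n2 / 2)), drop = FALSE]
}

# DFT frequency axis (Hz) in DC-centered order for n samples at spacing dt.
fftFreqCentered <- function(n, dt) {
    (seq_len(n) - 1L - floor(n / 2)) / (n * dt)
}

# 2-D FFT helpers operating on DC-centered arrays (image centered at
# floor(n/2) + 1). Unnormalized forward; the adjoint is fft(..., inverse).
fft2Centered <- function(x) fftshift2(stats::fft(ifftshift2(x)))

fft2CenteredAdjoint <- function(x) {
    fftshift2(stats::fft(ifftshift2(x), inverse = TRUE))
}

# Evaluate a piecewise-linear waveform defined by breakpoints (tb, gb) at
# times t (zero outside the span).
pwlEval <- function(tb, gb, t) {
    y <- stats::approx(tb, gb, xout = t, yleft = 0, yright = 0,
                       ties = "ordered")$y
    y
}

# Exact integral of a piecewise-linear waveform from tb[1] to each time t.
pwlIntegral <- function(tb, gb, t) {
    n <- length(tb)
    seg_area <- c(0, cumsum((gb[-1] + gb[-n]) / 2 * diff(tb)))
    idx <- findInterval(t, tb, rightmost.closed = TRUE)
    out <- numeric(length(t))
    inside <- idx >= 1L & idx < n
    i <- idx[inside]
    tloc <- t[inside] - tb[i]
    slope <- (gb[i + 1L] - gb[i]) / (tb[i + 1L] - tb[i])
    out[inside] <- seg_area[i] + gb[i] * tloc + slope * tloc^2 / 2
    out[t >= tb[n]] <- seg_area[n]
    out[t < tb[1L]] <- 0
    out
}

relErr <- function(a, b) {
    nb <- sqrt(sum(Mod(b)^2))
    if (nb == 0) sqrt(sum(Mod(a)^2)) else sqrt(sum(Mod(a - b)^2)) / nb
}

stopifnotPositive <- function(...) {
    args <- list(...)
    nm <- names(args)
    for (i in seq_along(args)) {
        if (!is.numeric(args[[i]]) || any(!is.finite(args[[i]])) ||
            any(args[[i]] <= 0)) {
            stop(sprintf("'%s' must be positive and finite", nm[i]),
                 call. = FALSE)
        }
    }
    invisible(TRUE)
}
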