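# 2-D non-uniform Fourier transform (type 2 forward / type 1 adjoint) by
# Kaiser-Bessel gridding on a 2x oversampled grid, with an exact-adjoint
# construction (the adjoint is the transpose of every linear step of the
# forward). A direct-summation evaluation is provided as the exact oracle
# for small grids.

NUFFT_J <- 8L                           # kernel full width (grid units)
NUFFT_OSF <- 2                          # grid oversampling factor
# Kaiser-Bessel shape parameter for (J, osf), Beatty et al. choice
NUFFT_BETA <- pi * sqrt((NUFFT_J / NUFFT_OSF)^2 *
                            (NUFFT_OSF - 0.5)^2 - 0.8)

# Continuous Fourier transform of the (unit-peak) Kaiser-Bessel kernel,
# evaluated at frequency nu (cycles per grid unit).
kbKernelHat <- function(nu, J = NUFFT_J, beta = NUFFT_BETA) {
    arg2 <- beta^2 - (pi * J * nu)^2
    out <- numeric(length(nu))
    pos <- arg2 > 0
    sq <- sqrt(abs(arg2))
    out[pos] <- sinh(sq[pos]) / sq[pos]
    out[!pos] <- ifelse(sq[!pos] == 0, 1, sin(sq[!pos]) / sq[!pos])
    out * J / besselI(beta, 0)
}

#' Plan a 2-D non-uniform Fourier transform
#'
#' Precomputes gridding coordinates and the deapodization profile for
#' sampling the spectrum of an n x n image (pixel size fov/n) at arbitrary
#' k-space positions (m^-1).
#'
#' @param kx,ky sample positions (m^-1), any shape (flattened).
#' @param fov field of view (m).
#' @param n image matrix size (even).
#' @return a plan for \code{\link{nufftForward}} / \code{\link{nufftAdjoint}}.
#' @export
nufftPlan <- function(kx, ky, fov, n) {
    if (n %% 2L != 0L) stop("matrix size must be even")
    delta <- fov / n
    wx <- 2 * pi * as.numeric(kx) * delta
    wy <- 2 * pi * as.numeric(ky) * delta
    if (any(abs(wx) > pi * (1 + 1e-9)) || any(abs(wy) > pi * (1 + 1e-9)))
        warning("trajectory exceeds the grid Nyquist band; aliasing expected")
    N <- as.integer(NUFFT_OSF * n)
    x <- seq_len(n) - 1L - n / 2
    dea1 <- kbKernelHat(x / N)
    list(u = wx * N / (2 * pi) + N / 2, v = wy * N / (2 * pi) + N / 2,
         n = as.integer(n), N = N, dea = outer(dea1, dea1),
         idx = (N / 2 - n / 2 + 1L):(N / 2 + n / 2), M = length(wx))
}

#' Forward (type 2) NUFFT: image to non-uniform k-space samples
#'
#' Evaluates F[j] = sum_x d[x] exp(-i 2 pi k_j . (x - c) * fov / n) over
#' pixel offsets x - c centered at floor(n/2).
#'
#' @param plan from \code{\link{nufftPlan}}.
#' @param img complex n x n matrix.
#' @return complex vector of samples.
#' @export
nufftForward <- function(plan, img) {
    stopifnot(nrow(img) == plan$n, ncol(img) == plan$n)
    P <- matrix(0i, plan$N, plan$N)
    P[plan$idx, plan$idx] <- img / plan$dea
    Fg <- fft2Centered(P)
    kb_interp_cpp(Fg, plan$u, plan$v, NUFFT_J, NUFFT_BETA)
}

#' Adjoint (type 1) NUFFT: non-uniform samples to image grid
#'
#' Exact adjoint of \code{\link{nufftForward}}.
#'
#' @param plan from \code{\link{nufftPlan}}.
#' @param vals complex sample vector.
#' @return complex n x n matrix.
#' @export
nufftAdjoint <- function(plan, vals) {
    stopifnot(length(vals) == plan$M)
    Fg <- kb_spread_cpp(as.complex(vals), plan$u, plan$v, plan$N,
                        NUFFT_J, NUFFT_BETA)
    P <- fft2CenteredAdjoint(Fg)
    P[plan$idx, plan$idx] / plan$dea
}

#' Direct-summation non-uniform DFT (exact oracle)
#'
#' Same contract as \code{\link{nufftForward}} / \code{\link{nufftAdjoint}}
#' but by direct summation; O(n^2 M), intended for grids up to ~64^2.
#'
#' @param img complex matrix (forward) / \code{vals} samples (adjoint).
#' @param kx,ky sample positions (m^-1).
#' @param fov field of view (m); \code{n} matrix size (adjoint).
#' @return samples (forward) or image (adjoint).
#' @export
nudftForward <- function(img, kx, ky, fov) {
    delta <- fov / nrow(img)
    nudft2_forward_cpp(img * (1 + 0i), 2 * pi * as.numeric(kx) * delta,
                       2 * pi * as.numeric(ky) * delta)
}

#' @rdname nudftForward
#' @param vals complex sample vector.
#' @export
nudftAdjoint <- function(vals, kx, ky, fov, n) {
    delta <- fov / n
    nudft2_adjoint_cpp(as.complex(vals), 2 * pi * as.numeric(kx) * delta,
                       2 * pi * as.numeric(ky) * delta, n, n)
}

#' Relative dot-product (adjointness) residual of an operator pair
#'
#' Draws random complex x and y (fixed seed) and reports
#' |<Fx, y> - <x, F^H y>| / (||Fx|| ||y||).
#'
#' @param forward,adjoint functions mapping image -> samples and back.
#' @param n image size; \code{m} number of samples; \code{seed} RNG seed.
#' @return nonnegative scalar.
#' @export
dotProductResidual <- function(forward, adjoint, n, m, seed = 1L) {
    set.seed(seed)
    x <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
    y <- complex(real = rnorm(m), imaginary = rnorm(m))
    Fx <- forward(x)
    Fhy <- adjoint(y)
    lhs <- sum(Conj(y) * Fx)
    rhs <- sum(Conj(Fhy) * x)
    Mod(lhs - rhs) / (sqrt(sum(Mod(Fx)^2)) * sqrt(sum(Mod(y)^2)))
}
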