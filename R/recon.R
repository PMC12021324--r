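# Stack-of-stars reconstruction: kz transform, k-space-center
# self-navigation, overlapped respiratory binning, radial density
# compensation, coil-map estimation, adjoint and iterative
# compressed-sensing reconstruction.

#' Inverse Fourier transform along the Cartesian kz dimension
#'
#' Unitary, DC-centered inverse DFT along the partition dimension; the
#' result indexes slices instead of partitions. A single partition is the
#' identity.
#'
#' @param y \linkS4class{AcquisitionKSpace} or a complex array
#'   [sample, spoke, kz, coil, echo].
#' @return complex array [sample, spoke, slice, coil, echo].
#' @export
kzTransform <- function(y) {
    arr <- if (is(y, "AcquisitionKSpace")) y@y else y
    d <- dim(arr)
    if (length(d) != 5L) stop("expected [sample, spoke, kz, coil, echo]")
    nKz <- d[3L]
    if (nKz == 1L) return(arr)
    perm <- aperm(arr, c(3L, 1L, 2L, 4L, 5L))
    dim(perm) <- c(nKz, prod(d[-3L]))
    sh <- c((ceiling(nKz / 2) + 1L):nKz, 1:ceiling(nKz / 2))  # ifftshift
    us <- c((floor(nKz / 2) + 1L):nKz, 1:floor(nKz / 2))      # fftshift
    out <- stats::mvfft(perm[sh, , drop = FALSE],
                        inverse = TRUE)[us, , drop = FALSE] / sqrt(nKz)
    dim(out) <- c(nKz, d[1L], d[2L], d[4L], d[5L])
    aperm(out, c(2L, 3L, 1L, 4L, 5L))
}

# Forward (unitary, centered) counterpart, for round-trip checks and the
# simulator.
kzTransformForward <- function(arr) {
    d <- dim(arr)
    nKz <- d[3L]
    if (nKz == 1L) return(arr)
    perm <- aperm(arr, c(3L, 1L, 2L, 4L, 5L))
    dim(perm) <- c(nKz, prod(d[-3L]))
    sh <- c((ceiling(nKz / 2) + 1L):nKz, 1:ceiling(nKz / 2))
    us <- c((floor(nKz / 2) + 1L):nKz, 1:floor(nKz / 2))
    out <- stats::mvfft(perm[sh, , drop = FALSE])[us, , drop = FALSE] /
        sqrt(nKz)
    dim(out) <- c(nKz, d[1L], d[2L], d[4L], d[5L])
    aperm(out, c(2L, 3L, 1L, 4L, 5L))
}

#' Extract the per-coil self-navigation signal
#'
#' For each spoke angle and coil: the mean magnitude over the
#' \code{centerSamples} readout points closest to the k-space center,
#' aggregated (mean) over partitions, followed by subtraction of a moving
#' average over neighboring spoke angles (window \code{navWindow},
#' edge-replicated).
#'
#' @param y \linkS4class{AcquisitionKSpace}.
#' @param cfg \linkS4class{ReconConfig}.
#' @param echo echo window of the referenced trajectory to use.
#' @return matrix [spoke, coil] with attribute \code{interval} when the
#'   acquisition times permit (the spoke-block spacing in seconds).
#' @export
extractNavigator <- function(y, cfg = ReconConfig(), echo = 1L) {
    stopifnot(is(y, "AcquisitionKSpace"))
    win <- y@traj@echoWindows[[echo]]
    smp <- win$start:win$end
    if (cfg@centerSamples > length(smp))
        stop("centerSamples exceeds the samples per spoke")
    kr <- sqrt(y@traj@kx[smp, 1L]^2 + y@traj@ky[smp, 1L]^2)
    sel <- smp[order(kr)[seq_len(cfg@centerSamples)]]
    d <- dim(y@y)
    nav <- matrix(apply(Mod(y@y[sel, , , , 1L, drop = FALSE]),
                        c(2L, 4L), mean), d[2L], d[4L])
    w <- min(cfg@navWindow, d[2L] - (1 - d[2L] %% 2L))
    if (w %% 2L == 0L) w <- w - 1L
    if (w >= 3L) {
        half <- w %/% 2L
        kern <- rep(1 / w, w)
        for (co in seq_len(ncol(nav))) {
            xp <- c(rep(nav[1L, co], half), nav[, co],
                    rep(nav[nrow(nav), co], half))
            ma <- stats::filter(xp, kern, sides = 2L)
            nav[, co] <- nav[, co] -
                as.numeric(ma)[(half + 1L):(half + nrow(nav))]
        }
    } else {
        nav <- sweep(nav, 2L, colMeans(nav))
    }
    tt <- y@times
    if (nrow(tt) > 1L)
        attr(nav, "interval") <- tt[2L, 1L] - tt[1L, 1L]
    nav
}

#' Derive the respiratory surrogate from the navigator matrix
#'
#' Scores each coil by spectral concentration in the respiratory band
#' (fraction of non-DC power within \code{respBand}), discards the
#' lower-scoring half, performs principal component analysis across the
#' retained coils and selects the first component -- falling back to the
#' second when the first fails an autocorrelation periodicity check. The
#' sign is fixed so that the most frequent extreme (the end-expiration
#' plateau) is the signal maximum (non-positive skewness).
#'
#' @param nav navigator matrix [spoke, coil] from
#'   \code{\link{extractNavigator}}.
#' @param interval navigator sampling interval (s); defaults to the
#'   matrix's \code{interval} attribute.
#' @param respBand respiratory frequency band (Hz).
#' @param minScore floor score below which no coil is considered to carry
#'   a respiratory signal.
#' @return a \linkS4class{RespiratorySignal}.
#' @export
deriveSurrogate <- function(nav, interval = attr(nav, "interval"),
                            respBand = c(0.1, 0.5), minScore = 0.05) {
    if (is.null(interval)) stop("navigator sampling interval required")
    nc <- ncol(nav)
    if (nc < 2L) stop("need at least 2 coils")
    ns <- nrow(nav)
    f <- (seq_len(ns) - 1L) / (ns * interval)
    f <- pmin(f, 1 / interval - f)              # fold to [0, Nyquist]
    inBand <- f >= respBand[1L] & f <= respBand[2L]
    scores <- vapply(seq_len(nc), function(co) {
        p <- Mod(stats::fft(nav[, co] - mean(nav[, co])))^2
        tot <- sum(p[f > 0])
        if (tot == 0) 0 else sum(p[inBand]) / tot
    }, numeric(1))
    if (all(scores < minScore))
        stop("no respiratory signal: all coil scores below the floor")
    keep <- order(scores, decreasing = TRUE)[seq_len(ceiling(nc / 2))]
    pc <- stats::prcomp(nav[, keep, drop = FALSE], center = TRUE,
                        scale. = FALSE)
    periodic <- function(x) {
        maxLag <- min(ns - 2L, ceiling(20 / interval))
        a <- stats::acf(x, lag.max = maxLag, plot = FALSE)$acf[-1L]
        lo <- max(2L, floor(1 / interval))      # ignore sub-second lags
        if (length(a) < lo) return(max(a))
        max(a[lo:length(a)])
    }
    comp <- 1L
    x <- pc$x[, 1L]
    if (ncol(pc$x) >= 2L && periodic(x) < 0.2) {
        comp <- 2L
        x <- pc$x[, 2L]
    }
    skew <- mean((x - mean(x))^3) / stats::sd(x)^3
    flipped <- skew > 0
    if (flipped) x <- -x
    new("RespiratorySignal", value = as.numeric(x), interval = interval,
        component = as.numeric(comp), flipped = flipped,
        coilScores = scores, keptCoils = as.integer(sort(keep)))
}

#' Sort spokes into overlapped respiratory bins
#'
#' Spokes are ranked by surrogate value (ties broken by acquisition
#' order); the primary bins are equal-count quantile groups. With overlap
#' o, the lowest-ranked fraction o of each primary bin additionally joins
#' the adjacent bin below and the highest-ranked fraction o the bin above
#' -- except the outer halves of the two extreme bins, which stay
#' single-membership. At the default o = 0.5 each primary bin is split
#' into two halves shared with its neighbors.
#'
#' @param s \linkS4class{RespiratorySignal} or numeric vector.
#' @param cfg \linkS4class{ReconConfig} (nBins, overlap <= 0.5).
#' @return a \linkS4class{BinAssignment}.
#' @export
binSpokes <- function(s, cfg = ReconConfig()) {
    v <- if (is(s, "RespiratorySignal")) s@value else as.numeric(s)
    N <- length(v)
    nb <- as.integer(cfg@nBins)
    o <- cfg@overlap
    if (o > 0.5) stop("overlap above 0.5 would put spokes in > 2 bins")
    rk <- order(v, seq_len(N))          # ascending, stable in time
    counts <- rep(N %/% nb, nb)
    if (N %% nb) counts[seq_len(N %% nb)] <- counts[seq_len(N %% nb)] + 1L
    ends <- cumsum(counts)
    starts <- c(1L, head(ends, -1L) + 1L)
    primary <- lapply(seq_len(nb), function(b) sort(rk[starts[b]:ends[b]]))
    members <- primary
    if (nb >= 2L && o > 0) {
        for (b in seq_len(nb)) {
            ranked <- rk[starts[b]:ends[b]]
            nShare <- round(counts[b] * o)
            if (nShare < 1L) next
            low <- ranked[seq_len(nShare)]
            high <- ranked[(counts[b] - nShare + 1L):counts[b]]
            if (b > 1L) members[[b - 1L]] <- c(members[[b - 1L]], low)
            if (b < nb) members[[b + 1L]] <- c(members[[b + 1L]], high)
        }
        members <- lapply(members, sort)
    }
    new("BinAssignment", primary = primary, members = members,
        nSpokes = as.numeric(N))
}

#' Radial density-compensation weights
#'
#' Ramp weights proportional to |k| with the local radial sample spacing,
#' scaled by the per-spoke angular share (2 pi / nSpokes for center-out
#' half spokes, pi / nSpokes for full spokes) so that the weighted adjoint
#' approximates the continuous inverse transform; the k-space-center
#' sample of a half spoke receives the area of its small disk divided
#' among all spokes.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param echo echo window index.
#' @return weight matrix [sample, spoke], nonnegative and finite.
#' @export
densityWeights <- function(traj, echo = 1L) {
    win <- traj@echoWindows[[echo]]
    smp <- win$start:win$end
    nSpokes <- length(traj@spokeAngles)
    if (!is.finite(traj@fov) || !is.finite(traj@matrixSize))
        stop("trajectory lacks fov/matrix geometry")
    delta <- traj@fov / traj@matrixSize
    # per-spoke angular share: half-gap to the angular neighbors (the
    # golden-angle ordering leaves unequal gaps); center-out half spokes
    # partition the full circle, full spokes (diameters) the half circle
    span <- if (isTRUE(win$halfSpoke)) 2 * pi else pi
    th <- traj@spokeAngles %% span
    o <- order(th)
    ths <- th[o]
    gaps <- diff(c(ths, ths[1L] + span))         # gap after each sorted spoke
    shares <- (gaps + c(gaps[nSpokes], gaps[-nSpokes])) / 2
    dthSpoke <- numeric(nSpokes)
    dthSpoke[o] <- shares
    W <- matrix(0, length(smp), nSpokes)
    for (sp in seq_len(nSpokes)) {
        dth <- dthSpoke[sp]
        px <- 2 * pi * delta * traj@kx[smp, sp]
        py <- 2 * pi * delta * traj@ky[smp, sp]
        r <- sqrt(px^2 + py^2)
        n <- length(r)
        # local spacing along the spoke (arc length, not radius, so the
        # center crossing of a full spoke keeps its finite spacing)
        dr <- numeric(n)
        if (n > 1L) {
            dr[2:(n - 1L)] <- sqrt((px[3:n] - px[1:(n - 2L)])^2 +
                                       (py[3:n] - py[1:(n - 2L)])^2) / 2
            dr[1L] <- sqrt((px[2L] - px[1L])^2 + (py[2L] - py[1L])^2)
            dr[n] <- sqrt((px[n] - px[n - 1L])^2 + (py[n] - py[n - 1L])^2)
        }
        w <- r * dr * dth / (2 * pi)^2
        ctr <- r < dr / 2
        if (any(ctr))
            w[ctr] <- pi * (dr[ctr] / 2)^2 * (dth / span) / (2 * pi)^2
        W[, sp] <- w
    }
    W
}

#' Estimate coil sensitivity maps from motion-averaged k-space
#'
#' Low-resolution per-coil images are formed by heavily apodizing the
#' central k-space (Gaussian in |k|) and gridding; the maps are each coil
#' image divided by the root-sum-of-squares image inside a support mask
#' (so their sum of squared magnitudes is exactly 1 there) and zero
#' outside.
#'
#' @param yAvg complex array [sample, spoke, coil] (one slice, one echo).
#' @param traj \linkS4class{Trajectory} (echo window matching yAvg).
#' @param n image matrix size.
#' @param echo echo window index.
#' @param apodFrac apodization width as a fraction of the Nyquist radius.
#' @param supportFrac support threshold as a fraction of the peak
#'   root-sum-of-squares intensity.
#' @return a \linkS4class{CoilMaps}.
#' @export
estimateCoilMaps <- function(yAvg, traj, n, echo = 1L, apodFrac = 0.15,
                             supportFrac = 0.12) {
    win <- traj@echoWindows[[echo]]
    smp <- win$start:win$end
    stopifnot(dim(yAvg)[1L] == length(smp))
    nCoils <- dim(yAvg)[3L]
    kx <- traj@kx[smp, , drop = FALSE]
    ky <- traj@ky[smp, , drop = FALSE]
    delta <- traj@fov / traj@matrixSize
    r <- 2 * pi * delta * sqrt(kx^2 + ky^2)
    apod <- exp(-(r / (apodFrac * pi))^2)
    W <- densityWeights(traj, echo) * apod
    plan <- nufftPlan(kx, ky, traj@fov, n)
    imgs <- array(0i, c(n, n, nCoils))
    for (co in seq_len(nCoils))
        imgs[, , co] <- nufftAdjoint(plan, as.vector(W * yAvg[, , co]))
    rss <- sqrt(apply(Mod(imgs)^2, c(1L, 2L), sum))
    if (max(rss) == 0) stop("degenerate input: empty support")
    support <- rss > supportFrac * max(rss)
    maps <- array(0i, c(n, n, nCoils))
    for (co in seq_len(nCoils)) {
        m <- imgs[, , co]
        m[!support] <- 0i
        m[support] <- m[support] / rss[support]
        maps[, , co] <- m
    }
    new("CoilMaps", maps = maps, support = support)
}

# Multi-coil forward/adjoint operators for one spoke subset.
mcForward <- function(plan, maps, img) {
    nCoils <- dim(maps)[3L]
    out <- matrix(0i, plan$M, nCoils)
    for (co in seq_len(nCoils))
        out[, co] <- nufftForward(plan, img * maps[, , co])
    out
}

mcAdjoint <- function(plan, maps, vals) {
    nCoils <- dim(maps)[3L]
    img <- matrix(0i, plan$n, plan$n)
    for (co in seq_len(nCoils))
        img <- img + Conj(maps[, , co]) * nufftAdjoint(plan, vals[, co])
    img
}

#' Motion-averaged adjoint (gridding) reconstruction
#'
#' Coil-combined adjoint NUFFT of the density-compensated data over all
#' spokes: d = sum_c C_c^* A^H (W y_c).
#'
#' @param y complex array [sample, spoke, coil] (one slice) or
#'   [sample, spoke, slice, coil] (looped over slices).
#' @param traj \linkS4class{Trajectory}.
#' @param maps \linkS4class{CoilMaps}.
#' @param weights density weights (default \code{\link{densityWeights}}).
#' @param echo echo window index.
#' @return an \linkS4class{ImageSeries}.
#' @export
reconAdjoint <- function(y, traj, maps, weights = NULL, echo = 1L) {
    win <- traj@echoWindows[[echo]]
    smp <- win$start:win$end
    if (length(dim(y)) == 3L) dim(y) <- c(dim(y)[1:2], 1L, dim(y)[3L])
    nSlices <- dim(y)[3L]
    n <- dim(maps@maps)[1L]
    if (is.null(weights)) weights <- densityWeights(traj, echo)
    plan <- nufftPlan(traj@kx[smp, , drop = FALSE],
                      traj@ky[smp, , drop = FALSE], traj@fov, n)
    out <- array(0i, c(n, n, nSlices, 1L))
    nCoils <- dim(y)[4L]
    for (sl in seq_len(nSlices)) {
        vals <- matrix(0i, prod(dim(weights)), nCoils)
        for (co in seq_len(nCoils))
            vals[, co] <- as.vector(weights * y[, , sl, co])
        out[, , sl, 1L] <- mcAdjoint(plan, maps@maps, vals)
    }
    vox <- traj@fov / n
    ImageSeries(out, voxelSize = c(vox, vox))
}

#' Respiratory-resolved compressed-sensing reconstruction
#'
#' Minimizes ||F(d, C) - y||^2 + lambda ||S(d)||_1 over the binned dynamic
#' images d, where F is the per-bin multi-coil NUFFT with coil maps C and
#' S is the first-order temporal difference across bins under an
#' epsilon-smoothed absolute value. Solved by nonlinear conjugate gradient
#' (Polak-Ribiere) with a backtracking Armijo line search; lambda is
#' \code{lambdaFrac} times the peak magnitude of the per-bin adjoint
#' initialization; the objective is recorded per iteration and is
#' nonincreasing.
#'
#' @param y complex array [sample, spoke, coil] (one slice, one echo).
#' @param traj \linkS4class{Trajectory}.
#' @param maps \linkS4class{CoilMaps}.
#' @param bins \linkS4class{BinAssignment}.
#' @param cfg \linkS4class{ReconConfig}.
#' @param echo echo window index.
#' @return list with \code{image} (an \linkS4class{ImageSeries} with a bin
#'   dimension), \code{objective} (per iteration, first entry the
#'   initialization) and \code{lambda}.
#' @export
reconCs <- function(y, traj, maps, bins, cfg = ReconConfig(), echo = 1L) {
    win <- traj@echoWindows[[echo]]
    smp <- win$start:win$end
    nb <- length(bins@members)
    n <- dim(maps@maps)[1L]
    nCoils <- dim(maps@maps)[3L]
    W <- densityWeights(traj, echo)
    nSpokes <- length(traj@spokeAngles)
    plans <- list(); yb <- list(); d <- array(0i, c(n, n, nb))
    for (b in seq_len(nb)) {
        sp <- bins@members[[b]]
        if (!length(sp)) stop("empty bin")
        plans[[b]] <- nufftPlan(traj@kx[smp, sp, drop = FALSE],
                                traj@ky[smp, sp, drop = FALSE],
                                traj@fov, n)
        yv <- y[, sp, , drop = FALSE]
        dim(yv) <- c(length(smp) * length(sp), nCoils)
        yb[[b]] <- yv
        wb <- as.vector(W[, sp, drop = FALSE]) * (nSpokes / length(sp))
        d[, , b] <- mcAdjoint(plans[[b]], maps@maps, wb * yv)
    }
    lambda <- cfg@lambdaFrac * max(Mod(d))
    eps2 <- (cfg@epsFrac * max(Mod(d)))^2
    objective <- function(dd) {
        fid <- 0
        for (b in seq_len(nb)) {
            r <- mcForward(plans[[b]], maps@maps, dd[, , b]) - yb[[b]]
            fid <- fid + sum(Mod(r)^2)
        }
        pen <- 0
        if (nb > 1L && lambda > 0)
            for (b in 2:nb)
                pen <- pen + sum(sqrt(Mod(dd[, , b] - dd[, , b - 1L])^2 +
                                          eps2))
        fid + lambda * pen
    }
    gradient <- function(dd) {
        g <- array(0i, dim(dd))
        for (b in seq_len(nb)) {
            r <- mcForward(plans[[b]], maps@maps, dd[, , b]) - yb[[b]]
            g[, , b] <- 2 * mcAdjoint(plans[[b]], maps@maps, r)
        }
        if (nb > 1L && lambda > 0) {
            for (b in 2:nb) {
                u <- dd[, , b] - dd[, , b - 1L]
                t <- u / sqrt(Mod(u)^2 + eps2)
                g[, , b] <- g[, , b] + lambda * t
                g[, , b - 1L] <- g[, , b - 1L] - lambda * t
            }
        }
        g
    }
    obj <- numeric(cfg@nIter + 1L)
    obj[1L] <- objective(d)
    g <- gradient(d)
    p <- -g
    alpha <- 1
    for (it in seq_len(cfg@nIter)) {
        gp <- Re(sum(Conj(g) * p))
        if (gp >= 0) { p <- -g; gp <- Re(sum(Conj(g) * p)) }
        # backtracking Armijo line search
        alpha <- alpha * 2
        fCur <- obj[it]
        accepted <- FALSE
        for (ls in seq_len(25L)) {
            dNew <- d + alpha * p
            fNew <- objective(dNew)
            if (is.finite(fNew) && fNew <= fCur + 1e-4 * alpha * gp) {
                accepted <- TRUE
                break
            }
            alpha <- alpha / 2
        }
        if (!accepted || fNew > fCur) {
            obj[(it + 1L):(cfg@nIter + 1L)] <- fCur
            break
        }
        d <- dNew
        gNew <- gradient(d)
        beta <- max(0, Re(sum(Conj(gNew) * (gNew - g))) /
                        max(Re(sum(Conj(g) * g)), 1e-300))
        p <- -gNew + beta * p
        g <- gNew
        obj[it + 1L] <- fNew
    }
    if (!is.finite(obj[cfg@nIter + 1L]))
        stop("divergence: non-finite objective")
    vox <- traj@fov / n
    img <- ImageSeries(array(d, c(n, n, 1L, nb)), voxelSize = c(vox, vox))
    list(image = img, objective = obj, lambda = lambda)
}
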