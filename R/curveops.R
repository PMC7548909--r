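#' Pre- and post-melt normalization windows
#'
#' Two temperature intervals flanking a melt transition. A straight line is
#' fitted to the signal inside each window; normalization rescales the
#' curve so the pre-melt line maps to 1 and the post-melt line to 0, the
#' convention used by high-resolution melt software. Both windows must
#' contain at least 3 grid points when applied to a curve.
#'
#' @param pre,post length-2 numeric intervals `c(low, high)` in degrees
#'   Celsius, with `pre` entirely below `post`
#' @return A validated `list(pre = , post = )`.
#' @export
meltWindows <- function(pre, post) {
    stopifnot(length(pre) == 2L, length(post) == 2L)
    b <- c(pre, post)
    if (any(!is.finite(b)) || any(diff(b) <= 0))
        stop("validation error: windows must satisfy pre[1] < pre[2] < post[1] < post[2]")
    list(pre = as.numeric(pre), post = as.numeric(post))
}

.windowIdx <- function(grid, window) {
    p <- gridPoints(grid)
    idx <- which(p >= window[1L] - 1e-9 & p <= window[2L] + 1e-9)
    if (length(idx) < 3L)
        stop("validation error: window [", window[1L], ", ", window[2L],
             "] covers fewer than 3 grid points")
    idx
}

#' Savitzky-Golay smoothing of a melt curve
#'
#' Least-squares polynomial filtering on the uniform grid; endpoints are
#' handled by the filter's reduced-window polynomial fits, so any signal
#' that is itself a polynomial of degree at most `polyorder` is reproduced
#' exactly. `window = 1` is the identity.
#'
#' @param curve a [MeltCurve-class]
#' @param window odd filter length in points, at least `polyorder + 2`
#' @param polyorder polynomial order
#' @return A smoothed [MeltCurve-class].
#' @export
smoothCurve <- function(curve, window = 7L, polyorder = 3L) {
    window <- as.integer(window)
    if (window %% 2L == 0L)
        stop("validation error: smoothing window must be odd")
    if (window == 1L)
        return(MeltCurve(curve@grid, curve@signal, "smoothed"))
    if (window < polyorder + 2L)
        stop("validation error: window must be at least polyorder + 2")
    if (window > length(curve@grid))
        stop("validation error: window exceeds curve length")
    sm <- signal::sgolayfilt(curve@signal, p = polyorder, n = window)
    MeltCurve(curve@grid, sm, "smoothed")
}

#' Negative first derivative, -d(RFU)/dT
#'
#' Central differences on interior points, one-sided differences at the
#' ends, sign-flipped so that melt transitions appear as positive peaks.
#'
#' @param curve a [MeltCurve-class] on a uniform grid
#' @return A [DerivativeCurve-class].
#' @export
negativeDerivative <- function(curve) {
    s <- curve@signal
    n <- length(s)
    if (n < 3L)
        stop("validation error: need at least 3 points for a derivative")
    h <- gridStep(curve@grid)
    d <- numeric(n)
    d[1L] <- (s[2L] - s[1L]) / h
    d[n] <- (s[n] - s[n - 1L]) / h
    i <- 2:(n - 1L)
    d[i] <- (s[i + 1L] - s[i - 1L]) / (2 * h)
    new("DerivativeCurve", grid = curve@grid, values = -d)
}

## topographic prominence of a local maximum
.prominence <- function(v, i) {
    h <- v[i]
    left <- if (i == 1L) h else {
        j <- (i - 1L):1L
        higher <- which(v[j] > h)
        if (length(higher)) min(v[j[seq_len(higher[1L])]]) else min(v[j])
    }
    right <- if (i == length(v)) h else {
        j <- (i + 1L):length(v)
        higher <- which(v[j] > h)
        if (length(higher)) min(v[j[seq_len(higher[1L])]]) else min(v[j])
    }
    h - max(left, right)
}

#' Detect melt peaks in a derivative curve
#'
#' Local maxima whose topographic prominence reaches
#' `minProminenceFrac` times the global maximum and whose height reaches
#' `minHeight` (an absolute floor in -dRFU/dT units; the pipeline default
#' of 8 suppresses noise-only peaks in template-free wells at the
#' simulator's RFU scale). Each peak is assigned a domain interval: the
#' boundary between adjacent peaks sits at the derivative minimum between
#' them, and the outermost boundaries are the grid ends.
#'
#' @param dcurve a [DerivativeCurve-class]
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   global maximum
#' @param minHeight absolute height floor (same units as the derivative)
#' @return A `data.frame` with columns `tm_c`, `height`, `prominence`,
#'   `domain_low`, `domain_high`, sorted by temperature; zero rows when no
#'   peak qualifies.
#' @export
findMeltPeaks <- function(dcurve, minProminenceFrac = 0.25, minHeight = 0) {
    v <- dcurve@values
    p <- gridPoints(dcurve@grid)
    n <- length(v)
    empty <- data.frame(tm_c = numeric(), height = numeric(),
                        prominence = numeric(), domain_low = numeric(),
                        domain_high = numeric())
    if (n < 3L) return(empty)
    cand <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                  v[2:(n - 1L)] >= v[3:n]) + 1L
    if (!length(cand)) return(empty)
    prom <- vapply(cand, function(i) .prominence(v, i), numeric(1))
    keep <- v[cand] >= minHeight & prom >= minProminenceFrac * max(v)
    cand <- cand[keep]; prom <- prom[keep]
    if (!length(cand)) return(empty)
    lows <- highs <- numeric(length(cand))
    for (k in seq_along(cand)) {
        lows[k] <- if (k == 1L) p[1L] else {
            between <- cand[k - 1L]:cand[k]
            p[between[which.min(v[between])]]
        }
        highs[k] <- if (k == length(cand)) p[n] else {
            between <- cand[k]:cand[k + 1L]
            p[between[which.min(v[between])]]
        }
    }
    data.frame(tm_c = p[cand], height = v[cand], prominence = prom,
               domain_low = lows, domain_high = highs)
}

#' Split a multiplex curve into per-amplicon sub-curves
#'
#' Assigns detected peaks to loci by melt-temperature order (the
#' lower-melting amplicon first) and cuts the curve at the inter-peak
#' derivative minima recorded in the peak table. When the number of peaks
#' does not match the number of expected amplicons the result carries the
#' QC flag `domain_count_mismatch` (and an empty list for zero peaks).
#'
#' @param curve a [MeltCurve-class]
#' @param peaks the peak table from [findMeltPeaks()]
#' @param loci expected amplicons in ascending Tm order
#' @return A named list of [MeltCurve-class] sub-curves with attribute
#'   `qcFlags`.
#' @export
splitDomains <- function(curve, peaks, loci = .LOCI) {
    flags <- character()
    if (nrow(peaks) != length(loci)) flags <- "domain_count_mismatch"
    if (nrow(peaks) == 0L)
        return(structure(list(), qcFlags = flags))
    peaks <- peaks[order(peaks$tm_c), , drop = FALSE]
    k <- min(nrow(peaks), length(loci))
    out <- lapply(seq_len(k), function(i)
        subsetCurve(curve, peaks$domain_low[i], peaks$domain_high[i]))
    names(out) <- loci[seq_len(k)]
    structure(out, qcFlags = flags)
}

#' Two-line melt-curve normalization
#'
#' Fits straight pre- and post-melt baselines to the signal inside the two
#' windows and rescales:
#' \deqn{\hat s(T) = \frac{s(T) - \ell_{post}(T)}{\ell_{pre}(T) -
#'   \ell_{post}(T)}}
#' so the pre-melt region sits at 1 and the post-melt region at 0. The two
#' baselines share one slope (the instrument's background drift is common
#' to both plateaus); fitting the slopes independently in two narrow
#' windows would amplify read noise roughly tenfold once the lines are
#' extrapolated to mid-domain. The transform is exactly invariant to
#' per-well amplitude scaling and to any added linear background. Output
#' values are winsorized to the valid normalized band \[-0.05, 1.05\];
#' only extreme noise excursions are affected.
#'
#' @param curve a [MeltCurve-class] spanning both windows
#' @param windows a [meltWindows()] pair
#' @param slope optional fixed background slope (RFU per degree Celsius),
#'   e.g. a whole-curve estimate from [backgroundSlope()]; when given only
#'   the two baseline levels are fitted in the windows. Narrow windows
#'   identify a slope poorly, so a whole-curve estimate is markedly more
#'   stable; both variants are exactly invariant to amplitude scaling and
#'   to added linear background.
#' @return A normalized [MeltCurve-class].
#' @export
normalizeCurve <- function(curve, windows, slope = NULL) {
    windows <- meltWindows(windows$pre, windows$post)
    p <- gridPoints(curve@grid)
    s <- curve@signal
    iPre <- .windowIdx(curve@grid, windows$pre)
    iPost <- .windowIdx(curve@grid, windows$post)
    if (is.null(slope)) {
        ## shared-slope, two-intercept fit: s = b0 + b1 T + A * [T in pre]
        idx <- c(iPre, iPost)
        X <- cbind(1, p[idx], rep(c(1, 0), c(length(iPre), length(iPost))))
        beta <- stats::lm.fit(X, s[idx])$coefficients
        b0 <- beta[1L]; b1 <- beta[2L]; amplitude <- beta[3L]
    } else {
        b1 <- slope
        b0 <- mean(s[iPost] - b1 * p[iPost])
        amplitude <- mean(s[iPre] - b1 * p[iPre]) - b0
    }
    if (!is.finite(amplitude) || amplitude <= 0)
        stop("normalization error: zero or negative dynamic range")
    norm <- (s - b0 - b1 * p) / amplitude
    MeltCurve(curve@grid, pmin(pmax(norm, -0.05), 1.05), "normalized")
}

#' Plate-level background slope
#'
#' The drifting pre-melt background has roughly one slope per well, but a
#' window fit sees too little temperature lever to pin it down: the
#' per-well estimate is several times noisier than the true well-to-well
#' slope variation, and its error bows the normalized curve between the
#' windows. The pipeline therefore normalizes every well -- including the
#' reference controls -- with one common slope, the plate-wide median of
#' the per-well window estimates: whatever error the common slope carries
#' distorts all curves identically and cancels in the difference curves,
#' while genuine per-well slope differences are small enough (a fraction
#' of an RFU per degree Celsius) that their residual effect is well below
#' the read noise.
#'
#' @param plate a [MeltPlate-class]
#' @param windows whole-curve pre/post windows (a [meltWindows()] pair)
#' @param wells wells to include (default all)
#' @return Median background slope in RFU per degree Celsius.
#' @export
plateBackgroundSlope <- function(plate, windows, wells = wellIds(plate)) {
    slopes <- vapply(wells, function(w)
        tryCatch(.windowSlope(wellCurve(plate, w), windows),
                 error = function(e) NA_real_), numeric(1))
    slopes <- slopes[is.finite(slopes)]
    if (!length(slopes))
        stop("normalization error: no well yields a background slope")
    stats::median(slopes)
}

## shared-slope, two-intercept OLS on the two windows; returns the slope
.windowSlope <- function(curve, windows) {
    windows <- meltWindows(windows$pre, windows$post)
    p <- gridPoints(curve@grid)
    iPre <- .windowIdx(curve@grid, windows$pre)
    iPost <- .windowIdx(curve@grid, windows$post)
    idx <- c(iPre, iPost)
    X <- cbind(1, p[idx], rep(c(1, 0), c(length(iPre), length(iPost))))
    stats::lm.fit(X, curve@signal[idx])$coefficients[[2L]]
}

## first downward crossing of `level`, linearly interpolated
.crossingTemp <- function(values, temps, level) {
    above <- values >= level
    i <- which(above[-length(values)] & !above[-1L])
    if (!length(i)) return(NA_real_)
    i <- i[1L]
    temps[i] + (values[i] - level) / (values[i] - values[i + 1L]) *
        (temps[i + 1L] - temps[i])
}

#' Melting temperature at 50 percent signal loss
#'
#' Normalizes the curve between its pre- and post-melt windows and returns
#' the temperature at which the normalized signal first falls through 0.5
#' (half the duplex denatured), linearly interpolated between grid points.
#'
#' @inheritParams normalizeCurve
#' @return Tm in degrees Celsius.
#' @export
tmAtHalfLoss <- function(curve, windows) {
    norm <- normalizeCurve(curve, windows)
    tm <- .crossingTemp(norm@signal, gridPoints(norm@grid), 0.5)
    if (is.na(tm))
        stop("no-Tm error: normalized signal never crosses 0.5")
    tm
}

#' Temperature-shift a normalized curve onto a reference
#'
#' Translates the sample curve along the temperature axis so its
#' `shiftLevel` helicity crossing coincides with the reference's, then
#' resamples it onto the reference grid by linear interpolation (ends held
#' at 1 and 0). The translation is clipped to `maxShift`; shifts beyond
#' the cap are treated as genotype signal rather than calibration error
#' and left uncorrected when estimated by [wellCalibration()]. A
#' precomputed `shift` (e.g. a per-well thermal calibration shared between
#' loci) bypasses the crossing estimate.
#'
#' @param norm,reference normalized [MeltCurve-class] objects on
#'   overlapping grids
#' @param shiftLevel helicity fraction in (0, 0.5) at which curves are
#'   registered
#' @param maxShift maximum translation in degrees Celsius
#' @param shift optional explicit translation in degrees Celsius
#'   (still clipped to `maxShift`)
#' @return A shifted [MeltCurve-class] on the reference grid.
#' @export
temperatureShift <- function(norm, reference, shiftLevel = 0.05,
                             maxShift = 1.0, shift = NULL) {
    if (is.null(shift)) {
        stopifnot(shiftLevel > 0, shiftLevel < 0.5)
        tS <- .crossingTemp(norm@signal, gridPoints(norm@grid), shiftLevel)
        tR <- .crossingTemp(reference@signal, gridPoints(reference@grid),
                            shiftLevel)
        if (is.na(tS) || is.na(tR))
            stop("shift error: no crossing at level ", shiftLevel)
        shift <- tR - tS
    }
    shift <- max(-maxShift, min(maxShift, shift))
    xout <- gridPoints(reference@grid)
    res <- stats::approx(gridPoints(norm@grid) + shift, norm@signal,
                         xout = xout, rule = 1)$y
    lowEnd <- xout < gridPoints(norm@grid)[1L] + shift
    res[is.na(res) & lowEnd] <- 1
    res[is.na(res)] <- 0
    out <- MeltCurve(reference@grid, pmin(pmax(res, -0.05), 1.05), "shifted")
    attr(out, "shift") <- shift
    out
}

#' Difference curve against a reference
#'
#' Pointwise difference between a shifted, normalized sample curve and the
#' reference curve of one amplicon domain; the classifier's input.
#'
#' @param shifted,reference [MeltCurve-class] objects on the same grid
#' @param locus `"ZAP70"` or `"IKBKB"`
#' @return A [DifferenceCurve-class].
#' @export
differenceCurve <- function(shifted, reference, locus) {
    if (!sameGrid(shifted@grid, reference@grid))
        stop("validation error: grid mismatch between curve and reference")
    new("DifferenceCurve", grid = reference@grid,
        values = shifted@signal - reference@signal, locus = locus)
}
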