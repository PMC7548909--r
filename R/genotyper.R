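## genotype composition implied by a control role
.roleGenotypes <- function(role) {
    switch(role,
        control_wild_type = c(ZAP70 = "wild_type", IKBKB = "wild_type"),
        control_het_zap70 = c(ZAP70 = "heterozygous", IKBKB = "wild_type"),
        control_hom_zap70 = c(ZAP70 = "homozygous_affected", IKBKB = "wild_type"),
        control_het_ikbkb = c(ZAP70 = "wild_type", IKBKB = "heterozygous"),
        control_hom_ikbkb = c(ZAP70 = "wild_type", IKBKB = "homozygous_affected"),
        NULL)
}

.zeroDiff <- function(grid, locus)
    new("DifferenceCurve", grid = grid, values = numeric(length(grid)),
        locus = locus)

## local descent rate |d signal/dT| of a normalized curve at temperature t:
## the precision of a crossing estimate is proportional to this slope
.crossingSlope <- function(curve, t) {
    if (!is.finite(t)) return(NA_real_)
    p <- gridPoints(curve@grid)
    i <- max(1L, min(length(p) - 1L, findInterval(t, p)))
    abs(curve@signal[i] - curve@signal[i + 1L]) / (p[i + 1L] - p[i])
}

## smooth + QC + per-locus normalization for one raw well curve.
## Baselines are fitted on the raw signal (window points carry independent
## read noise, so the fit averages properly) and the normalized curve is
## smoothed afterwards.
.prepareWell <- function(raw, config, bgSlope = NULL) {
    flags <- character()
    sm <- smoothCurve(raw, config$curve$smooth_window,
                      config$curve$smooth_polyorder)
    pre <- mean(sm@signal[.windowIdx(sm@grid, config$windows$whole_pre)])
    post <- mean(sm@signal[.windowIdx(sm@grid, config$windows$whole_post)])
    if (pre - post < config$call$min_amplitude)
        return(list(norm = NULL, calTm = NULL, flags = "low_amplitude"))
    peaks <- findMeltPeaks(negativeDerivative(sm),
                           config$curve$peak_min_prominence_frac,
                           config$curve$peak_min_height)
    if (nrow(peaks) != length(config$loci))
        flags <- c(flags, "domain_count_mismatch")
    levels <- config$curve$calibration_levels
    norm <- list()
    calTm <- calSlope <- matrix(NA_real_, length(levels),
                                length(config$loci),
                                dimnames = list(NULL, config$loci))
    for (locus in config$loci) {
        d <- .locusDomain(config, locus)
        nc <- tryCatch({
            nr <- normalizeCurve(subsetCurve(raw, d[1L], d[2L]),
                                 .locusWindows(config, locus),
                                 slope = bgSlope)
            v <- smoothCurve(nr, config$curve$norm_smooth_window,
                             config$curve$smooth_polyorder)@signal
            MeltCurve(nr@grid, pmin(pmax(v, -0.05), 1.05), "normalized")
        }, error = function(e) NULL)
        if (is.null(nc)) { flags <- c(flags, "shift_error"); next }
        norm[[locus]] <- nc
        calTm[, locus] <- vapply(levels, function(l)
            .crossingTemp(nc@signal, gridPoints(nc@grid), l), numeric(1))
        calSlope[, locus] <- vapply(seq_along(levels), function(k)
            .crossingSlope(nc, calTm[k, locus]), numeric(1))
    }
    calTm <- calTm[, names(norm), drop = FALSE]
    calSlope <- calSlope[, names(norm), drop = FALSE]
    list(norm = norm, calTm = calTm, calSlope = calSlope,
         flags = unique(flags))
}

#' Per-well thermal calibration shift
#'
#' One thermal calibration offset applies to a whole well, while genotype
#' effects displace the melt-crossing temperatures locus-specifically.
#' The well is registered at two helicity levels per locus; each
#' genotype-pair hypothesis predicts all four crossings up to one shared
#' offset, using the genotype displacement profiles learned from control
#' wells (`displacement`). Hypotheses are scored by a Gaussian
#' model-selection criterion: quadratic misfit of each registration point
#' at its measured precision (read noise over the crossing descent rate,
#' plus a systematic term `sysSd` for composite variant transitions,
#' whose shape makes their registration more sensitive to normalization
#' error), a Gaussian prior on the shared offset (`priorSd`, the
#' instrument's thermal calibration spread -- this is what stops a
#' genotype displacement from passing as pure calibration), and a rarity
#' penalty per variant locus. A definite alignment additionally requires
#' the winner to beat, by `vetoGap` log-units (20:1 odds), every
#' alternative hypothesis whose applied shift at a locus differs by more
#' than `vetoShift`; otherwise that locus is marked ambiguous and the
#' caller refuses to genotype it. Inadmissible or inconsistent patterns
#' degrade to an uncorrected well, except that an internally consistent
#' all-wild-type pattern beyond the cap is applied clipped (pure
#' calibration drift).
#'
#' @param calTm matrix of the well's calibration crossing temperatures,
#'   rows = calibration levels, columns = loci (a plain named vector is
#'   accepted as a single-level registration)
#' @param refCalTm the same for the reference
#' @param maxShift calibration cap in degrees Celsius
#' @param displacement per-locus list of genotype crossing-displacement
#'   matrices, rows = levels, columns = genotypes (as in the
#'   `tmDisplacement` slot of [MeltReference-class]); an optional
#'   `"slope"` attribute of the same shape carries the crossing descent
#'   rates used for precision weighting
#' @param discTol coarse sanity bound (degrees Celsius) on the raw
#'   spread among a hypothesis' implied offsets; the discriminating gate
#'   is the standardized `zTol`
#' @param calSlope matrix of the well's crossing descent rates (per
#'   degree Celsius), same shape as `calTm`
#' @param zTol maximum tolerated standardized inconsistency
#' @param noiseSd nominal per-point noise of a normalized curve
#' @param priorSd prior s.d. of the well-vs-reference thermal offset
#' @param sysSd systematic registration s.d. added for variant-genotype
#'   crossings
#' @param vetoGap log-score margin required over call-changing
#'   alternatives
#' @param vetoShift applied-shift difference (degrees Celsius) above
#'   which an alternative counts as call-changing
#' @return Named numeric: the shift in degrees Celsius to apply at each
#'   locus, with attribute `"ambiguous"` marking loci whose alignment is
#'   not decided at the required odds. Loci hypothesized wild type align
#'   by their own measured shift (pure calibration); variant-hypothesized
#'   loci borrow the wild-type-anchored offset so their genotype
#'   displacement remains measured rather than forced.
#' @export
wellCalibration <- function(calTm, refCalTm, maxShift = 0.35,
                            displacement = NULL, discTol = 0.5,
                            calSlope = NULL, zTol = 3.5, noiseSd = 0.012,
                            priorSd = 0.06, sysSd = 0.08, vetoGap = 3,
                            vetoShift = 0.1) {
    asMat <- function(x) {
        if (is.matrix(x)) x
        else matrix(x, 1L, dimnames = list(NULL, names(x)))
    }
    calTm <- asMat(calTm); refCalTm <- asMat(refCalTm)
    shifts <- refCalTm[, colnames(calTm), drop = FALSE] - calTm
    loci <- colnames(shifts)[colSums(is.finite(shifts)) > 0L]
    if (!length(loci)) return(NULL)
    shifts <- shifts[, loci, drop = FALSE]
    if (is.null(calSlope))
        calSlope <- matrix(NA_real_, nrow(shifts), length(loci),
                           dimnames = list(NULL, loci))
    else calSlope <- asMat(calSlope)[, loci, drop = FALSE]
    clip <- function(x) pmax(-maxShift, pmin(maxShift, x))
    ## per-crossing jitter variance: read noise over the descent rate on
    ## both sides, plus a systematic term for variant registrations
    pointVar <- function(wellSlope, muSlope, variant) {
        vw <- ifelse(is.finite(wellSlope) & wellSlope > 0,
                     (noiseSd / wellSlope)^2, (noiseSd / 0.3)^2)
        vm <- ifelse(is.finite(muSlope) & muSlope > 0,
                     (noiseSd / muSlope)^2, (noiseSd / 0.3)^2)
        vw + vm + ifelse(variant, sysSd^2, 0)
    }
    muMat <- function(l) {
        m <- displacement[[l]]
        if (is.matrix(m)) m else matrix(m, 1L, dimnames = list(NULL, names(m)))
    }
    wMean <- function(x, v) {
        keep <- is.finite(x)
        sum(x[keep] / v[keep]) / sum(1 / v[keep])
    }
    if (is.null(displacement) || length(loci) == 1L) {
        ## degraded mode: nearest-genotype offset at each available locus
        cand <- unlist(lapply(loci, function(l) {
            mu <- if (is.null(displacement)) 0 else colMeans(muMat(l))
            mean(shifts[, l][is.finite(shifts[, l])]) - mu
        }))
        cal <- cand[which.min(abs(cand))]
        if (abs(cal) > maxShift) cal <- 0
        return(stats::setNames(rep(unname(cal), length(loci)), loci))
    }
    muA <- muMat(loci[1L]); muB <- muMat(loci[2L])
    slA <- attr(displacement[[loci[1L]]], "slope")
    slB <- attr(displacement[[loci[2L]]], "slope")
    if (is.null(slA)) slA <- muA * NA
    if (is.null(slB)) slB <- muB * NA
    hyp <- expand.grid(a = seq_len(ncol(muA)), b = seq_len(ncol(muB)))
    nH <- nrow(hyp)
    genoA <- colnames(muA)[hyp$a]; genoB <- colnames(muB)[hyp$b]
    nonWt <- (genoA != "wild_type") + (genoB != "wild_type")
    nLev <- nrow(shifts)
    disc <- discZ <- cal <- score <- numeric(nH)
    applied <- matrix(NA_real_, nH, 2L)
    lociShift <- function(i, var) {
        x <- shifts[, i]
        v <- pointVar(calSlope[, i], calSlope[, i], var)
        wMean(x, v)
    }
    for (h in seq_len(nH)) {
        d <- c(shifts[, 1L] - muA[, hyp$a[h]], shifts[, 2L] - muB[, hyp$b[h]])
        v <- c(pointVar(calSlope[, 1L], slA[, hyp$a[h]],
                        genoA[h] != "wild_type"),
               pointVar(calSlope[, 2L], slB[, hyp$b[h]],
                        genoB[h] != "wild_type"))
        keep <- is.finite(d)
        dk <- d[keep]; vk <- v[keep]
        cal[h] <- sum(dk / vk) / (sum(1 / vk) + 1 / priorSd^2)
        disc[h] <- max(dk) - min(dk)
        discZ[h] <- max(abs(dk - cal[h]) / sqrt(vk))
        score[h] <- sum((dk - cal[h])^2 / (2 * vk)) +
            cal[h]^2 / (2 * priorSd^2) + 2.2 * nonWt[h]
        ## the shift this hypothesis would apply at each locus
        isWt <- c(genoA[h], genoB[h]) == "wild_type"
        anchor <- if (any(isWt)) {
            dd <- unlist(lapply(which(isWt), function(i) shifts[, i]))
            vv <- unlist(lapply(which(isWt), function(i)
                pointVar(calSlope[, i], calSlope[, i], FALSE)))
            wMean(dd, vv)
        } else cal[h]
        applied[h, ] <- clip(vapply(1:2, function(i)
            if (isWt[i]) lociShift(i, FALSE) else anchor, numeric(1)))
    }
    consistent <- disc <= discTol & discZ <= zTol
    ok <- abs(cal) <= maxShift & consistent
    if (!any(ok)) {
        ## an all-wild-type pattern that is internally consistent but
        ## beyond the cap is pure calibration drift: apply it clipped.
        ## Any other pattern is left uncorrected rather than guessed.
        allWt <- nonWt == 0L
        if (any(consistent & allWt)) {
            cw <- mean(unlist(lapply(loci, function(l)
                shifts[, l][is.finite(shifts[, l])])))
            return(stats::setNames(rep(clip(cw), length(loci)), loci))
        }
        return(stats::setNames(rep(0, length(loci)), loci))
    }
    score[!ok] <- Inf
    best <- which.min(score)
    ## ambiguity veto: an alternative within vetoGap log-units whose
    ## applied shift differs materially makes that locus a refusal
    ambiguous <- vapply(1:2, function(i) any(
        is.finite(score) & score - score[best] < vetoGap &
            abs(applied[, i] - applied[best, i]) > vetoShift), logical(1))
    out <- stats::setNames(applied[best, ], loci)
    attr(out, "ambiguous") <- stats::setNames(ambiguous, loci)
    out
}

## full chain for one well against a built reference; `calibration`
## overrides the estimated thermal shift (used for control wells whose
## genotype, and hence wild-type anchor locus, is known)
.processWell <- function(raw, ref, config, calibration = NULL) {
    prep <- .prepareWell(raw, config, ref@bgSlope)
    if (is.null(prep$norm) || !length(prep$norm))
        return(list(diffs = list(), flags = prep$flags, shift = NA_real_))
    cal <- if (!is.null(calibration)) calibration
           else wellCalibration(prep$calTm, ref@calTm,
                                config$curve$max_shift, ref@tmDisplacement,
                                calSlope = prep$calSlope)
    if (is.null(cal))
        return(list(diffs = list(),
                    flags = unique(c(prep$flags, "shift_error")),
                    shift = NA_real_))
    if (length(cal) == 1L && is.null(names(cal)))
        cal <- stats::setNames(rep(cal, length(prep$norm)), names(prep$norm))
    amb <- attr(cal, "ambiguous")
    diffs <- list()
    for (locus in names(prep$norm)) {
        s <- if (locus %in% names(cal)) cal[[locus]] else NA_real_
        if (!is.finite(s) ||
            (!is.null(amb) && isTRUE(amb[[locus]]))) {
            prep$flags <- unique(c(prep$flags, "shift_error"))
            next
        }
        d <- tryCatch({
            shifted <- temperatureShift(prep$norm[[locus]],
                                        ref@curves[[locus]],
                                        maxShift = config$curve$max_shift,
                                        shift = s)
            ## genotypes are compared on the inter-window melt region only
            dd <- .diffDomain(config, locus)
            differenceCurve(subsetCurve(shifted, dd[1L], dd[2L]),
                            subsetCurve(ref@curves[[locus]], dd[1L], dd[2L]),
                            locus)
        }, error = function(e) NULL)
        if (is.null(d)) {
            prep$flags <- unique(c(prep$flags, "shift_error"))
            next
        }
        diffs[[locus]] <- d
    }
    list(diffs = diffs, flags = prep$flags, shift = cal)
}

#' Build the control-anchored reference for a plate
#'
#' Processes the plate's control wells through the melt-analysis chain.
#' The per-locus wild-type reference curve is the pointwise mean of the
#' normalized wild-type control curves after thermal calibration (two
#' passes: a provisional mean anchors the calibration, then the calibrated
#' curves are re-averaged). Difference-curve centroids are then learned
#' for every genotype with a control on the plate; the wild-type centroid
#' is the zero curve by construction. Controls failing QC are excluded and
#' recorded, never silently dropped.
#'
#' @param plate a [MeltPlate-class]
#' @param sheet a sample sheet (see [readSampleSheet()])
#' @param config run configuration ([defaultRunConfig()])
#' @return A [MeltReference-class].
#' @export
buildReference <- function(plate, sheet, config = defaultRunConfig()) {
    sheet <- validateSampleSheet(sheet)
    missing <- setdiff(sheet$well, wellIds(plate))
    if (length(missing))
        stop("validation error: sheet wells absent from plate: ",
             paste(missing, collapse = ", "))
    ctrl <- sheet[startsWith(sheet$role, "control_"), , drop = FALSE]
    wtWells <- ctrl$well[ctrl$role == "control_wild_type"]
    if (!length(wtWells))
        stop("reference error: at least one control_wild_type well is required")

    ## one common background slope for the whole plate: its error is
    ## shared by every well and the reference, so it cancels in the
    ## difference curves
    whole <- meltWindows(config$windows$whole_pre, config$windows$whole_post)
    bgSlope <- plateBackgroundSlope(plate, whole,
                                    sheet$well[sheet$role != "no_template"])

    excluded <- character()
    prep <- list()
    for (w in ctrl$well) {
        pr <- .prepareWell(wellCurve(plate, w), config, bgSlope)
        bad <- intersect(pr$flags, c("low_amplitude", "shift_error"))
        if (length(bad) || length(pr$norm) < length(config$loci)) {
            excluded[w] <- paste(unique(c(bad, pr$flags)), collapse = ";")
        } else prep[[w]] <- pr
    }
    wtUse <- intersect(wtWells, names(prep))
    if (!length(wtUse))
        stop("reference error: no wild-type control passed QC")

    ## pass 1: provisional per-locus mean of normalized wild-type controls
    domains <- lapply(stats::setNames(config$loci, config$loci),
                      function(l) .locusDomain(config, l))
    windows <- lapply(stats::setNames(config$loci, config$loci),
                      function(l) .locusWindows(config, l))
    meanCurve <- function(curves) {
        vals <- rowMeans(vapply(curves, slot, numeric(length(curves[[1L]]@grid)),
                                "signal"))
        MeltCurve(curves[[1L]]@grid, pmin(pmax(vals, -0.05), 1.05),
                  "normalized")
    }
    levels <- config$curve$calibration_levels
    crossings <- function(curve) vapply(levels, function(l)
        .crossingTemp(curve@signal, gridPoints(curve@grid), l), numeric(1))
    prov <- list()
    provTm <- matrix(NA_real_, length(levels), length(config$loci),
                     dimnames = list(NULL, config$loci))
    for (locus in config$loci) {
        prov[[locus]] <- meanCurve(lapply(prep[wtUse],
                                          function(p) p$norm[[locus]]))
        provTm[, locus] <- crossings(prov[[locus]])
    }
    ## a control's calibration is anchored on its known wild-type loci:
    ## those align by their own half-melt shift, variant loci borrow the
    ## mean wild-type shift (so their displacement stays measurable)
    ctrlShifts <- function(w, refTm) {
        have <- colnames(prep[[w]]$calTm)
        refTm[, have, drop = FALSE] - prep[[w]]$calTm
    }
    ctrlAnchor <- function(w, refTm) {
        role <- ctrl$role[match(w, ctrl$well)]
        wtLoci <- names(which(.roleGenotypes(role) == "wild_type"))
        s <- ctrlShifts(w, refTm)
        s <- s[, intersect(wtLoci, colnames(s)), drop = FALSE]
        mean(s[is.finite(s)])
    }
    ctrlCalibration <- function(w, refTm) {
        role <- ctrl$role[match(w, ctrl$well)]
        genos <- .roleGenotypes(role)
        s <- ctrlShifts(w, refTm)
        anchor <- ctrlAnchor(w, refTm)
        out <- vapply(colnames(s), function(l) {
            if (genos[[l]] == "wild_type" && any(is.finite(s[, l])))
                mean(s[, l][is.finite(s[, l])])
            else anchor
        }, numeric(1))
        stats::setNames(pmax(-config$curve$max_shift,
                             pmin(config$curve$max_shift, out)),
                        colnames(s))
    }
    ## pass 2: calibrate each wild-type control to the provisional mean
    curves <- list()
    calTm <- refSlope <- matrix(NA_real_, length(levels),
                                length(config$loci),
                                dimnames = list(NULL, config$loci))
    for (locus in config$loci) {
        aligned <- lapply(wtUse, function(w)
            temperatureShift(prep[[w]]$norm[[locus]], prov[[locus]],
                             maxShift = config$curve$max_shift,
                             shift = ctrlCalibration(w, provTm)[[locus]]))
        curves[[locus]] <- meanCurve(aligned)
        calTm[, locus] <- crossings(curves[[locus]])
        refSlope[, locus] <- vapply(seq_along(levels), function(k)
            .crossingSlope(curves[[locus]], calTm[k, locus]), numeric(1))
    }
    ## genotype crossing displacements (and their descent rates) learned
    ## from the control wells; the wild-type column's rates come from the
    ## reference curves themselves
    tmDisp <- lapply(stats::setNames(config$loci, config$loci), function(l) {
        m <- matrix(0, length(levels), 1L, dimnames = list(NULL, "wild_type"))
        attr(m, "slope") <- matrix(refSlope[, l], ncol = 1L,
                                   dimnames = list(NULL, "wild_type"))
        m
    })
    for (w in names(prep)) {
        role <- ctrl$role[match(w, ctrl$well)]
        genos <- .roleGenotypes(role)
        for (locus in names(which(genos != "wild_type"))) {
            if (!locus %in% colnames(prep[[w]]$calTm)) next
            g <- genos[[locus]]
            mu <- (calTm[, locus] - prep[[w]]$calTm[, locus]) -
                ctrlAnchor(w, calTm)
            sl <- prep[[w]]$calSlope[, locus]
            m <- tmDisp[[locus]]; slopes <- attr(m, "slope")
            if (g %in% colnames(m)) {
                m[, g] <- (m[, g] + mu) / 2
                slopes[, g] <- (slopes[, g] + sl) / 2
            } else {
                m <- cbind(m, matrix(mu, ncol = 1L,
                                     dimnames = list(NULL, g)))
                slopes <- cbind(slopes, matrix(sl, ncol = 1L,
                                               dimnames = list(NULL, g)))
            }
            attr(m, "slope") <- slopes
            tmDisp[[locus]] <- m
        }
    }
    ref <- new("MeltReference", loci = config$loci, domains = domains,
               windows = windows, bgSlope = bgSlope,
               curves = curves, calTm = calTm,
               centroids = lapply(domains, function(d) list()),
               tmDisplacement = tmDisp,
               withinControl = stats::setNames(rep(0, length(config$loci)),
                                               config$loci),
               controlWells = list(), excluded = excluded)

    ## centroids: every control genotype observed on the plate
    centroids <- lapply(stats::setNames(config$loci, config$loci),
                        function(l) list())
    diffsByRole <- list()
    for (w in names(prep)) {
        role <- ctrl$role[match(w, ctrl$well)]
        pw <- .processWell(wellCurve(plate, w), ref, config,
                           calibration = ctrlCalibration(w, calTm))
        diffsByRole[[role]] <- c(diffsByRole[[role]],
                                 stats::setNames(list(pw$diffs), w))
    }
    metric <- config$call$metric
    within <- stats::setNames(rep(0, length(config$loci)), config$loci)
    for (locus in config$loci) {
        wtDiffs <- lapply(diffsByRole[["control_wild_type"]],
                          function(d) d[[locus]])
        within[locus] <- max(vapply(wtDiffs, function(d)
            curveDistance(d, .zeroDiff(d@grid, locus), metric), numeric(1)))
        for (role in setdiff(names(diffsByRole), "control_wild_type")) {
            g <- .roleGenotypes(role)[[locus]]
            if (g == "wild_type") next
            ds <- lapply(diffsByRole[[role]], function(d) d[[locus]])
            vals <- rowMeans(vapply(ds, slot,
                                    numeric(length(ds[[1L]]@grid)), "values"))
            centroids[[locus]][[g]] <- new("DifferenceCurve",
                                           grid = ds[[1L]]@grid,
                                           values = vals, locus = locus)
        }
    }
    ref@centroids <- centroids
    ref@withinControl <- within
    ref@controlWells <- split(intersect(ctrl$well, names(prep)),
                              ctrl$role[ctrl$well %in% names(prep)])
    ref
}

setMethod("show", "MeltReference", function(object) {
    cat("MeltReference\n")
    for (locus in object@loci) {
        cat(sprintf("  %s: domain [%.1f, %.1f] C, calibration crossing %.2f C, centroids: %s\n",
                    locus, object@domains[[locus]][1L],
                    object@domains[[locus]][2L], object@calTm[1L, locus],
                    paste(c("wild_type", names(object@centroids[[locus]])),
                          collapse = ", ")))
    }
    if (length(object@excluded))
        cat("  excluded controls:",
            paste(names(object@excluded), collapse = ", "), "\n")
})

#' Distance between two difference curves
#'
#' `max_abs` is the maximum absolute pointwise difference (matching the
#' visual band separation of genotype clusters); `rms` the root mean
#' square. Both are symmetric and zero iff the curves are equal.
#'
#' @param a,b [DifferenceCurve-class] objects on the same grid
#' @param metric `"max_abs"` or `"rms"`
#' @return Non-negative scalar distance.
#' @export
curveDistance <- function(a, b, metric = c("max_abs", "rms")) {
    metric <- match.arg(metric)
    if (!sameGrid(a@grid, b@grid))
        stop("validation error: grid mismatch between difference curves")
    d <- a@values - b@values
    if (metric == "max_abs") max(abs(d)) else sqrt(mean(d^2))
}

#' Classify one difference curve against the reference centroids
#'
#' Nearest-centroid call over the genotype centroids available for the
#' locus, with confidence \eqn{1 - d_1/(d_1 + d_2)} (nearest vs
#' second-nearest distance). The call degrades to `no_call` when the
#' confidence falls below the configured floor or the nearest distance
#' exceeds the outlier threshold (`outlier_multiplier` times the maximum
#' within-control distance, floored at `outlier_min`). With no
#' heterozygous/homozygous controls on the plate the decision is two-way:
#' a well within the wild-type threshold is called wild type, anything
#' else is a `no_call` flagged `no_controls` -- a non-wild-type sample is
#' never guessed.
#'
#' @param diff a [DifferenceCurve-class]
#' @param ref a [MeltReference-class]
#' @param config run configuration
#' @return `list(call, confidence, distances, flags)`.
#' @export
classifyWell <- function(diff, ref, config = defaultRunConfig()) {
    locus <- diff@locus
    metric <- config$call$metric
    floorConf <- config$call$confidence_floor
    threshold <- max(config$call$outlier_multiplier *
                         ref@withinControl[[locus]],
                     config$call$outlier_min)
    cents <- ref@centroids[[locus]]
    dists <- c(wild_type = curveDistance(diff, .zeroDiff(diff@grid, locus),
                                         metric))
    for (g in intersect(.GENOTYPES, names(cents)))
        dists[g] <- curveDistance(diff, cents[[g]], metric)

    flags <- character()
    if (length(dists) == 1L) {
        ## two-way: wild type vs not-wild-type (no genotype to assign)
        conf <- 1 - dists[[1L]] / (dists[[1L]] + threshold)
        if (dists[[1L]] <= threshold && conf >= floorConf) {
            call <- "wild_type"
        } else {
            call <- "no_call"
            flags <- "no_controls"
        }
    } else {
        ord <- order(dists)
        d1 <- dists[[ord[1L]]]; d2 <- dists[[ord[2L]]]
        conf <- if (d1 + d2 == 0) 1 else 1 - d1 / (d1 + d2)
        call <- names(dists)[ord[1L]]
        if (conf < floorConf || d1 > threshold) call <- "no_call"
        if (length(dists) < length(.GENOTYPES) && call == "no_call")
            flags <- "no_controls"
    }
    list(call = call, confidence = unname(conf), distances = dists,
         flags = flags)
}

#' Call genotypes for a whole plate
#'
#' Runs the full chain for every non-no-template well: smoothing, negative
#' derivative, peak QC, per-domain normalization, thermal calibration,
#' temperature shift, difference curve and nearest-centroid
#' classification. Every processing anomaly becomes a QC flag on the
#' affected rows, never a silent drop; the returned report carries a run
#' log in `attr(, "log")` with per-category counts. The chain is fully
#' deterministic: identical plate and configuration give an identical
#' report.
#'
#' @param plate a [MeltPlate-class]
#' @param sheet a sample sheet
#' @param config run configuration
#' @return A call-report `data.frame` (`well, sample, locus, call,
#'   confidence, qc_flags`), one row per well and locus.
#' @export
callPlate <- function(plate, sheet, config = defaultRunConfig()) {
    sheet <- validateSampleSheet(sheet)
    ref <- buildReference(plate, sheet, config)
    target <- sheet[sheet$role != "no_template", , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(target))) {
        w <- target$well[i]
        pw <- .processWell(wellCurve(plate, w), ref, config)
        for (locus in config$loci) {
            d <- pw$diffs[[locus]]
            if (is.null(d)) {
                rows[[length(rows) + 1L]] <- data.frame(
                    well = w, sample = target$sample[i], locus = locus,
                    call = "no_call", confidence = 0,
                    qc_flags = paste(pw$flags, collapse = ";"))
                next
            }
            cl <- classifyWell(d, ref, config)
            rows[[length(rows) + 1L]] <- data.frame(
                well = w, sample = target$sample[i], locus = locus,
                call = cl$call, confidence = cl$confidence,
                qc_flags = paste(unique(c(pw$flags, cl$flags)),
                                 collapse = ";"))
        }
    }
    report <- do.call(rbind, rows)
    rownames(report) <- NULL
    counts <- lapply(stats::setNames(config$loci, config$loci), function(l)
        table(factor(report$call[report$locus == l], levels = .CALLS)))
    attr(report, "log") <- list(
        n_wells = nrow(target),
        no_template_wells = sheet$well[sheet$role == "no_template"],
        call_counts = counts,
        flagged = report[nzchar(report$qc_flags),
                         c("well", "locus", "qc_flags")],
        excluded_controls = ref@excluded,
        within_control_distance = ref@withinControl,
        reference_cal_tm = ref@calTm)
    report
}

#' Score calls against known genotypes
#'
#' Exact-match concordance per locus and overall; `no_call` always counts
#' as discordant (a screening no-call is a failed ascertainment, not a
#' partial success).
#'
#' @param report a call report (all report samples must appear in `truth`)
#' @param truth `data.frame` with columns `sample`, `zap70`, `ikbkb`
#' @return A [ConcordanceSummary-class].
#' @export
scoreConcordance <- function(report, truth) {
    report <- .validateCallReport(report)
    if (nrow(report) == 0L)
        stop("validation error: empty call report")
    stopifnot(is.data.frame(truth),
              all(c("sample", "zap70", "ikbkb") %in% names(truth)))
    missing <- setdiff(report$sample, truth$sample)
    if (length(missing))
        stop("validation error: sample(s) missing from truth: ",
             paste(missing, collapse = ", "))
    expected <- vapply(seq_len(nrow(report)), function(i) {
        truth[[tolower(report$locus[i])]][match(report$sample[i],
                                                truth$sample)]
    }, character(1))
    ok <- report$call == expected
    perLocus <- vapply(stats::setNames(.LOCI, .LOCI), function(l)
        mean(ok[report$locus == l]), numeric(1))
    confusion <- lapply(stats::setNames(.LOCI, .LOCI), function(l) {
        sel <- report$locus == l
        table(truth = factor(expected[sel], levels = .GENOTYPES),
              call = factor(report$call[sel], levels = .CALLS))
    })
    new("ConcordanceSummary", nSamples = nrow(report),
        nConcordant = sum(ok), accuracy = mean(ok),
        perLocus = perLocus, confusion = confusion)
}

setMethod("show", "ConcordanceSummary", function(object) {
    cat(sprintf("ConcordanceSummary: %d/%d concordant (accuracy %.4f)\n",
                object@nConcordant, object@nSamples, object@accuracy))
    for (l in names(object@perLocus))
        cat(sprintf("  %s: %.4f\n", l, object@perLocus[l]))
})
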