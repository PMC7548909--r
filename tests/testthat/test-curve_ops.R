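test_that("Savitzky-Golay smoothing reproduces polynomials and preserves transitions", {
    g <- defaultGrid()
    t <- gridPoints(g)
    poly <- MeltCurve(g, 2 + 0.5 * t - 0.01 * t^2 + 1e-4 * t^3)
    sm <- smoothCurve(poly, 7, 3)
    expect_equal(curveSignal(sm), curveSignal(poly), tolerance = 1e-8)
    expect_equal(curveStage(sm), "smoothed")

    # window 1 is the identity
    noisy <- MeltCurve(g, rnorm(101))
    expect_identical(curveSignal(smoothCurve(noisy, 1)), curveSignal(noisy))

    # a noiseless logistic is barely distorted at window 7, order 3:
    # under half a percent of amplitude at the assay transition width,
    # and under a tenth of a percent for a 0.6 C transition
    lc <- logisticCurve(g, tm = 85, width = 0.35, amplitude = 1, baseline = 0)
    expect_lt(max(abs(curveSignal(smoothCurve(lc, 7, 3)) - curveSignal(lc))),
              5e-3)
    lc6 <- logisticCurve(g, tm = 85, width = 0.6, amplitude = 1, baseline = 0)
    expect_lt(max(abs(curveSignal(smoothCurve(lc6, 7, 3)) - curveSignal(lc6))),
              1e-3)

    expect_error(smoothCurve(lc, 6, 3), "odd")
    expect_error(smoothCurve(lc, 3, 3), "polyorder")
})

test_that("the negative derivative flips melt transitions into positive peaks", {
    g <- defaultGrid()
    t <- gridPoints(g)
    lin <- MeltCurve(g, 100 - 2 * t)
    expect_equal(negativeDerivative(lin)@values, rep(2, 101))
    expect_equal(negativeDerivative(MeltCurve(g, rep(7, 101)))@values,
                 rep(0, 101))

    lc <- logisticCurve(g, tm = 85, width = 0.35, amplitude = 100, baseline = 0)
    d <- negativeDerivative(lc)
    expect_lt(abs(gridPoints(g)[which.max(d@values)] - 85), 0.2 + 1e-9)

    short <- MeltCurve(gridFromPoints(c(80, 80.2)), c(1, 0))
    expect_error(negativeDerivative(short), "3 points")
})

test_that("peak finding and domain splitting follow the valley rule", {
    g <- defaultGrid()
    t <- gridPoints(g)
    two <- MeltCurve(g, 100 / (1 + exp((t - 81) / 0.35)) +
                         100 / (1 + exp((t - 87) / 0.35)))
    pk <- findMeltPeaks(negativeDerivative(two), 0.25, 0)
    expect_equal(nrow(pk), 2L)
    expect_equal(pk$tm_c, c(81, 87), tolerance = 0.21)
    expect_true(all(pk$domain_low < pk$tm_c & pk$tm_c < pk$domain_high))
    # the shared boundary sits at the derivative valley between the peaks
    expect_equal(pk$domain_high[1], pk$domain_low[2])
    expect_equal(pk$domain_high[1], 84, tolerance = 0.5)

    doms <- splitDomains(two, pk)
    expect_named(doms, c("ZAP70", "IKBKB"))
    expect_length(attr(doms, "qcFlags"), 0L)
    expect_equal(gridStop(curveGrid(doms$ZAP70)), pk$domain_high[1])
    expect_equal(gridStart(curveGrid(doms$IKBKB)), pk$domain_high[1])

    one <- logisticCurve(g, tm = 85, amplitude = 100, baseline = 0)
    pk1 <- findMeltPeaks(negativeDerivative(one), 0.25, 0)
    expect_equal(nrow(pk1), 1L)
    d1 <- splitDomains(one, pk1)
    expect_equal(attr(d1, "qcFlags"), "domain_count_mismatch")
    expect_length(d1, 1L)

    d0 <- splitDomains(one, pk1[0, ])
    expect_length(d0, 0L)
    expect_equal(attr(d0, "qcFlags"), "domain_count_mismatch")
})

test_that("pure-noise wells rarely produce spurious peaks at pipeline thresholds", {
    cfg <- defaultRunConfig()
    spurious <- 0L
    for (k in 1:100) {
        set.seed(30000 + k)
        w <- simulateWell(NA, NA)    # template-free well
        pk <- findMeltPeaks(negativeDerivative(smoothCurve(w)),
                            0.25, cfg$curve$peak_min_height)
        if (nrow(pk) > 0L) spurious <- spurious + 1L
    }
    expect_lte(spurious, 5L)
})

test_that("half-loss Tm is the interpolated 50% crossing", {
    g <- defaultGrid()
    win <- defaultWindows()
    lc <- logisticCurve(g, tm = 85, width = 0.35, amplitude = 120,
                        baseline = 10, slope = -0.1)
    expect_lt(abs(tmAtHalfLoss(lc, win) - 85), 0.05)

    # symmetric bracketing: 0.55 at 84.9 and 0.45 at 85.1 interpolate to 85
    expect_equal(scidHRM:::.crossingTemp(c(0.55, 0.45), c(84.9, 85.1), 0.5),
                 85)

    expect_error(tmAtHalfLoss(MeltCurve(g, rep(50, 101)), win),
                 "dynamic range")
})

test_that("normalization pins the windows at 1 and 0 and is exactly invariant", {
    g <- defaultGrid()
    win <- defaultWindows()
    base <- logisticCurve(g, tm = 85, width = 0.35, amplitude = 100,
                          baseline = 7, slope = -0.12)
    norm <- normalizeCurve(base, win)
    preIdx <- scidHRM:::.windowIdx(g, win$pre)
    postIdx <- scidHRM:::.windowIdx(g, win$post)
    expect_equal(mean(curveSignal(norm)[preIdx]), 1, tolerance = 1e-6)
    expect_equal(mean(curveSignal(norm)[postIdx]), 0, tolerance = 1e-6)

    # invariance to amplitude scaling and any added linear background
    t <- gridPoints(g)
    warped <- MeltCurve(g, 3.7 * curveSignal(base) + 41 - 0.8 * t)
    expect_equal(curveSignal(normalizeCurve(warped, win)),
                 curveSignal(norm), tolerance = 1e-9)
    # and identically with a fixed background slope supplied
    expect_equal(curveSignal(normalizeCurve(warped, win, slope = 3.7 * -0.12 - 0.8)),
                 curveSignal(normalizeCurve(base, win, slope = -0.12)),
                 tolerance = 1e-9)

    expect_error(normalizeCurve(MeltCurve(g, rep(4, 101)), win),
                 "dynamic range")
})

test_that("temperature shifting recovers translations and flags missing crossings", {
    refc <- unitLogistic(tm = 85)
    # identical curve: zero shift, output equals input
    out <- temperatureShift(refc, refc)
    expect_equal(attr(out, "shift"), 0, tolerance = 1e-9)
    expect_equal(curveSignal(out), curveSignal(refc), tolerance = 1e-9)

    # a +0.4 C translated copy is recovered with shift -0.4
    moved <- unitLogistic(tm = 85.4)
    back <- temperatureShift(moved, refc)
    expect_equal(attr(back, "shift"), -0.4, tolerance = 1e-3)
    expect_lt(max(abs(curveSignal(back) - curveSignal(refc))), 1e-6)

    # an explicit shift bypasses the crossing estimate and is clipped
    forced <- temperatureShift(moved, refc, maxShift = 0.1, shift = -0.4)
    expect_equal(attr(forced, "shift"), -0.1)

    flat <- MeltCurve(defaultGrid(), rep(1, 101), "normalized")
    expect_error(temperatureShift(flat, refc), "shift error")
})

test_that("difference curves subtract pointwise on a common grid", {
    refc <- unitLogistic(tm = 85)
    expect_equal(max(abs(diffValues(differenceCurve(refc, refc, "ZAP70")))), 0)

    other <- unitLogistic(tm = 84.2)
    d <- differenceCurve(other, refc, "IKBKB")
    expect_equal(diffValues(d), curveSignal(other) - curveSignal(refc))
    expect_equal(diffLocus(d), "IKBKB")

    sub <- subsetCurve(refc, 80, 90)
    expect_error(differenceCurve(sub, refc, "ZAP70"), "grid mismatch")
})

test_that("a heterozygous sample diverges visibly from the wild-type reference", {
    cfg <- defaultRunConfig()
    cohort <- rbind(tinyCohort(2),
                    data.frame(sample = "HET", zap70 = "heterozygous",
                               ikbkb = "wild_type", risk_locus = "ZAP70",
                               role = "unknown"))
    sim <- simulatePlate(cohort, noise = zeroNoise(), seed = 4)
    ref <- buildReference(sim$plate, sim$sheet, cfg)
    hetWell <- sim$sheet$well[sim$sheet$sample == "HET"]
    wtWell <- sim$sheet$well[sim$sheet$sample == "U01"]
    pwHet <- scidHRM:::.processWell(wellCurve(sim$plate, hetWell), ref, cfg)
    pwWt <- scidHRM:::.processWell(wellCurve(sim$plate, wtWell), ref, cfg)
    expect_gt(max(abs(diffValues(pwHet$diffs$ZAP70))), 0.05)
    expect_lt(max(abs(diffValues(pwWt$diffs$ZAP70))), 1e-6)
})

test_that("Tm at half loss matches the derivative peak within one grid step", {
    g <- defaultGrid()
    win <- defaultWindows()
    set.seed(77)
    for (i in 1:25) {
        tm <- runif(1, 80, 90)
        w <- runif(1, 0.3, 0.6)
        lc <- logisticCurve(g, tm = tm, width = w, amplitude = 100,
                            baseline = 5, slope = -0.1)
        tmHalf <- tmAtHalfLoss(lc, win)
        d <- negativeDerivative(smoothCurve(lc))
        tmPeak <- gridPoints(g)[which.max(d@values)]
        expect_lt(abs(tmHalf - tmPeak), 0.2 + 1e-9)
    }
})
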