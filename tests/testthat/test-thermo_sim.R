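revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

test_that("duplex thermodynamics sum stacks and initiation terms", {
    params <- nnParameters()
    # "AT": two A.T initiations plus the single AT stack
    expect_equal(nnDuplexThermo("AT", params),
                 c(dH = 2 * 2.3 - 7.2, dS = 2 * 4.1 - 20.4))

    # brute-force oracle: tabulate dimers and add terminal corrections
    oracle <- function(seq) {
        b <- strsplit(seq, "")[[1]]
        dimers <- paste0(head(b, -1), b[-1])
        canon <- vapply(dimers, function(d)
            if (d %in% names(params$stackDH)) d else revcomp(d), "")
        counts <- table(canon)
        ends <- b[c(1, length(b))]
        init <- vapply(ends, function(e)
            if (e %in% c("G", "C")) params$initGC else params$initAT,
            numeric(2))
        c(dH = sum(params$stackDH[names(counts)] * as.integer(counts)) +
              sum(init["dh", ]),
          dS = sum(params$stackDS[names(counts)] * as.integer(counts)) +
              sum(init["ds", ]))
    }
    set.seed(11)
    for (n in c(2, 5, 18, 60)) {
        s <- randomSeq(n)
        expect_equal(nnDuplexThermo(s, params), oracle(s))
    }

    expect_error(nnDuplexThermo("A"), "length")
    expect_error(nnDuplexThermo("ACGX"), "A, C, G, T")
})

test_that("duplex symmetry: Tm of a sequence equals its reverse complement", {
    params <- nnParameters()
    set.seed(42)
    for (i in 1:50) {
        s <- randomSeq(sample(8:40, 1))
        expect_equal(primerTm(s, params), primerTm(revcomp(s), params),
                     tolerance = 1e-10)
    }
})

test_that("primer Tms reproduce the published assay primers within 0.5 C", {
    published <- c(AGGAATCTCGCCTTCTTCC = 56.62,   # IKBKB forward
                   CTGGATGCTGTGCCAGAC = 58.10,    # IKBKB reverse
                   TGAGGAGGAGGACACTGG = 57.13,    # ZAP70 forward
                   TTGCCCTGCTCGATGAAG = 57.38)    # ZAP70 reverse
    params <- nnParameters()
    for (s in names(published))
        expect_lt(abs(primerTm(s, params) - published[[s]]), 0.5)
})

test_that("appending GC strictly increases Tm", {
    params <- nnParameters()
    set.seed(7)
    for (i in 1:20) {
        s <- randomSeq(sample(10:30, 1))
        expect_gt(primerTm(paste0(s, "GC"), params), primerTm(s, params))
    }
})

test_that("genotypes map to the expected duplex species", {
    amps <- scidAmplicons()
    expect_lt(length(amps$ZAP70@wtSequence), 100L)
    expect_lt(length(amps$IKBKB@wtSequence), 100L)
    # the dupG mutant is one base longer; the G>A substitution is not
    expect_equal(length(mutantSequence(amps$IKBKB)),
                 length(amps$IKBKB@wtSequence) + 1L)
    expect_equal(length(mutantSequence(amps$ZAP70)),
                 length(amps$ZAP70@wtSequence))

    wt <- speciesForGenotype(amps$ZAP70, "wild_type")
    expect_equal(nrow(wt), 1L)
    expect_equal(wt$fraction, 1)
    expect_equal(wt$label, "wt_homoduplex")

    het <- speciesForGenotype(amps$IKBKB, "heterozygous")
    expect_equal(nrow(het), 4L)
    expect_equal(het$fraction, rep(0.25, 4))
    expect_equal(sum(het$fraction), 1)

    hom <- speciesForGenotype(amps$ZAP70, "homozygous_affected")
    expect_equal(nrow(hom), 1L)
    # G>A removes a G:C pairing, so the mutant homoduplex melts lower
    expect_lt(hom$tm_c, wt$tm_c)
    # the IKBKB duplication adds a G:C pairing and melts higher
    expect_gt(ampliconTm(amps$IKBKB, mutant = TRUE), ampliconTm(amps$IKBKB))
    # heteroduplexes are destabilized below the homoduplex mean
    expect_lt(het$tm_c[3], mean(het$tm_c[1:2]))

    expect_error(speciesForGenotype(amps$ZAP70, "compound"), "genotype")
})

test_that("noiseless wells show two melt domains at the configured Tms", {
    cfg <- defaultRunConfig()
    set.seed(1)
    w <- simulateWell("wild_type", "wild_type", noise = zeroNoise())
    pk <- findMeltPeaks(negativeDerivative(smoothCurve(w)),
                        cfg$curve$peak_min_prominence_frac,
                        cfg$curve$peak_min_height)
    expect_equal(nrow(pk), 2L)
    amps <- scidAmplicons()
    expect_lt(abs(pk$tm_c[1] - ampliconTm(amps$ZAP70)), 0.2 + 1e-9)
    expect_lt(abs(pk$tm_c[2] - ampliconTm(amps$IKBKB)), 0.2 + 1e-9)

    # baseline-subtracted zero-noise signal is non-increasing
    t <- gridPoints(curveGrid(w))
    base <- cfg$sim$baseline_rfu + mean(c(-0.2, -0.05)) * (t - t[1])
    expect_true(all(diff(curveSignal(w) - base) <= 1e-12))
})

test_that("simulation is reproducible: same seed gives identical curves", {
    set.seed(99); a <- simulateWell("heterozygous", "wild_type")
    set.seed(99); b <- simulateWell("heterozygous", "wild_type")
    expect_identical(curveSignal(a), curveSignal(b))

    s1 <- simulatePlate(tinyCohort(), seed = 5)
    s2 <- simulatePlate(tinyCohort(), seed = 5)
    expect_identical(plateSignals(s1$plate), plateSignals(s2$plate))
    expect_identical(s1$sheet, s2$sheet)
})

test_that("shrinking heteroduplex destabilization converges to the homoduplex mixture", {
    cfg <- defaultRunConfig()
    mixCurve <- function(deltaZ) {
        cfg$sim$delta_zap70 <- deltaZ
        set.seed(3)
        curveSignal(simulateWell("heterozygous", "wild_type",
                                 noise = zeroNoise(), config = cfg))
    }
    # 50/50 homoduplex mixture: two species at fraction 0.5 is what a
    # vanishing destabilization approaches
    target <- local({
        amps <- scidAmplicons()
        t <- gridPoints(defaultGrid())
        tmW <- ampliconTm(amps$ZAP70); tmM <- ampliconTm(amps$ZAP70, TRUE)
        base <- cfg$sim$baseline_rfu + mean(c(-0.2, -0.05)) * (t - t[1])
        helix <- function(tm) 1 / (1 + exp((t - tm) / cfg$sim$width))
        iTm <- ampliconTm(amps$IKBKB)
        base + 50 * (0.5 * helix(tmW) + 0.5 * helix(tmM)) + 50 * helix(iTm)
    })
    errs <- vapply(c(-3, -1.5, -0.5), function(d) max(abs(mixCurve(d) - target)),
                   numeric(1))
    expect_true(all(diff(errs) < 0))
})

test_that("the noisy simulator is unbiased around the zero-noise curve", {
    # the tolerance is scaled by the additive read-noise s.d., so the
    # check isolates that component: all other nuisances off
    mid <- mean(c(-0.2, -0.05))
    additive <- noiseModel(rfuSigma = 0.01, amplitudeCv = 0,
                           baselineSlopeRange = c(mid, mid),
                           tempOffsetSigma = 0)
    clean <- curveSignal(simulateWell("wild_type", "heterozygous",
                                      noise = zeroNoise()))
    nseeds <- 500
    acc <- 0
    for (k in seq_len(nseeds)) {
        set.seed(20000 + k)
        acc <- acc + curveSignal(simulateWell("wild_type", "heterozygous",
                                              noise = additive))
    }
    tol <- 3 * (0.01 * 100) / sqrt(200)   # 3 sigma at a 200-seed scale
    expect_lt(max(abs(acc / nseeds - clean)), tol)

    # the full noise model is also unbiased, within the wider sampling
    # error contributed by amplitude and background variation
    accF <- 0
    for (k in seq_len(nseeds)) {
        set.seed(40000 + k)
        accF <- accF + curveSignal(simulateWell("wild_type", "heterozygous"))
    }
    expect_lt(max(abs(accF / nseeds - clean)), 2)
})

test_that("cohort specifications match the validation study design", {
    v <- validationCohort()
    expect_equal(nrow(v), 46L)
    expect_equal(sum(v$risk_locus == "ZAP70" & v$zap70 == "homozygous_affected"), 3L)
    expect_equal(sum(v$risk_locus == "ZAP70" & v$zap70 == "heterozygous"), 6L)
    expect_equal(sum(v$risk_locus == "ZAP70" & v$zap70 == "wild_type"), 1L)
    expect_equal(sum(v$risk_locus == "IKBKB" & v$ikbkb == "homozygous_affected"), 2L)
    expect_equal(sum(v$risk_locus == "IKBKB" & v$ikbkb == "heterozygous"), 14L)
    expect_equal(sum(v$risk_locus == "IKBKB" & v$ikbkb == "wild_type"), 20L)
    # at-risk samples are wild type at the other locus
    expect_true(all(v$ikbkb[v$risk_locus == "ZAP70"] == "wild_type"))
    expect_true(all(v$zap70[v$risk_locus == "IKBKB"] == "wild_type"))

    ctl <- controlCohort(60)
    expect_equal(nrow(ctl), 60L)
    expect_true(all(ctl$zap70 == "wild_type" & ctl$ikbkb == "wild_type"))
})

test_that("plates carry controls, truth and extensible well names", {
    sim <- simulatePlate(tinyCohort(3), seed = 2)
    expect_equal(ncol(sim$plate), 3L + 8L)   # cohort plus control block
    expect_equal(nrow(sim$truth), 3L)
    expect_true("no_template" %in% sim$sheet$role)
    expect_equal(sum(sim$sheet$role == "control_wild_type"), 3L)

    # >96 wells extend the naming scheme rather than failing
    big <- simulatePlate(mixedCohort(150), seed = 2)
    expect_equal(ncol(big$plate), 158L)
    expect_false(anyDuplicated(wellIds(big$plate)) > 0)

    # no-template wells are baseline plus noise: the peak finder sees nothing
    cfg <- defaultRunConfig()
    ntcWell <- sim$sheet$well[sim$sheet$role == "no_template"]
    dc <- negativeDerivative(smoothCurve(wellCurve(sim$plate, ntcWell)))
    pk <- findMeltPeaks(dc, cfg$curve$peak_min_prominence_frac,
                        cfg$curve$peak_min_height)
    expect_equal(nrow(pk), 0L)
})
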