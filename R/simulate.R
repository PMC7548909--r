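#' Instrument noise model for the simulator
#'
#' Captures the nuisance variation the analysis chain must undo: additive
#' Gaussian read noise, per-amplicon amplification-yield variation (the
#' "variable intensity of the starting signal" that makes normalization
#' necessary), a drifting pre-melt background, and a per-well thermal
#' calibration offset.
#'
#' @param rfuSigma additive Gaussian s.d. as a fraction of the nominal
#'   pre-melt amplitude
#' @param amplitudeCv coefficient of variation of the per-well, per-amplicon
#'   amplitude (lognormal, mean 1)
#' @param baselineSlopeRange range of the linear background slope in RFU per
#'   degree Celsius (uniform draw)
#' @param tempOffsetSigma s.d. of the per-well temperature calibration
#'   offset in degrees Celsius
#' @return A validated list of class `"NoiseModel"`.
#' @examples
#' noiseModel()     # assay defaults
#' zeroNoise()      # deterministic: all variation off, slope at mid-range
#' @export
noiseModel <- function(rfuSigma = 0.01, amplitudeCv = 0.15,
                       baselineSlopeRange = c(-0.2, -0.05),
                       tempOffsetSigma = 0.05) {
    stopifnot(rfuSigma >= 0, amplitudeCv >= 0, tempOffsetSigma >= 0,
              length(baselineSlopeRange) == 2L,
              baselineSlopeRange[1L] <= baselineSlopeRange[2L])
    structure(list(rfuSigma = rfuSigma, amplitudeCv = amplitudeCv,
                   baselineSlopeRange = baselineSlopeRange,
                   tempOffsetSigma = tempOffsetSigma),
              class = "NoiseModel")
}

#' @rdname noiseModel
#' @export
zeroNoise <- function() {
    mid <- mean(c(-0.2, -0.05))
    noiseModel(0, 0, c(mid, mid), 0)
}

## logistic helicity: fraction of duplex still paired at temperature T
.helicity <- function(temp, tm, width) 1 / (1 + exp((temp - tm) / width))

## Run code with a private, restored RNG stream.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

## Species tables for all genotypes at both loci, computed once per run.
.speciesTables <- function(config, amplicons = scidAmplicons(),
                           params = nnParameters()) {
    out <- list()
    for (locus in .LOCI) {
        delta <- if (locus == "ZAP70") config$sim$delta_zap70
                 else config$sim$delta_ikbkb
        out[[locus]] <- lapply(stats::setNames(.GENOTYPES, .GENOTYPES),
            function(g) speciesForGenotype(
                amplicons[[locus]], g, params,
                destabilizationDelta = delta, width = config$sim$width,
                oligoConc = config$thermo$oligo_conc,
                monovalent = config$thermo$monovalent))
    }
    out
}

#' Simulate one multiplex melt curve
#'
#' The raw signal is a constant floor plus a drifting linear background,
#' plus, for each amplicon, an amplitude times the fraction-weighted sum of
#' logistic helicity transitions of its duplex species, plus additive read
#' noise:
#' \deqn{s(T) = b_0 + m (T - T_0) + \sum_a A_a \sum_k f_k\,
#'   \theta(T; T_{m,k} + \delta, w_k) + \varepsilon(T)}
#' where \eqn{\theta} decreases from 1 to 0 and \eqn{\delta} is the well's
#' thermal calibration offset. Draws come from the current RNG stream, so
#' identical seeds reproduce identical curves bitwise.
#'
#' @param zap70Genotype,ikbkbGenotype genotype at each locus, or `NA` for a
#'   no-template well
#' @param grid acquisition [TemperatureGrid-class]
#' @param noise a [noiseModel()]
#' @param config run configuration ([defaultRunConfig()])
#' @param species precomputed species tables (internal use; computed from
#'   the bundled amplicons when `NULL`)
#' @return A raw [MeltCurve-class].
#' @examples
#' set.seed(1)
#' simulateWell("wild_type", "heterozygous", noise = zeroNoise())
#' @export
simulateWell <- function(zap70Genotype, ikbkbGenotype, grid = defaultGrid(),
                         noise = noiseModel(), config = defaultRunConfig(),
                         species = NULL) {
    for (g in c(zap70Genotype, ikbkbGenotype))
        if (!is.na(g) && !g %in% .GENOTYPES)
            stop("validation error: unknown genotype: ", g)
    if (is.null(species)) species <- .speciesTables(config)
    temp <- gridPoints(grid)
    nominal <- config$sim$amplitude
    perAmp <- nominal / 2

    ## draw all nuisance terms in a fixed order (stream stability)
    cv <- noise$amplitudeCv
    amps <- if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(2L, meanlog = -sdlog^2 / 2, sdlog = sdlog) * perAmp
    } else { stats::rlnorm(2L, 0, 0) * perAmp }
    slope <- stats::runif(1L, noise$baselineSlopeRange[1L],
                          noise$baselineSlopeRange[2L])
    offset <- stats::rnorm(1L, 0, noise$tempOffsetSigma)
    eps <- stats::rnorm(length(temp), 0, noise$rfuSigma * nominal)

    sig <- config$sim$baseline_rfu + slope * (temp - temp[1L])
    geno <- c(ZAP70 = zap70Genotype, IKBKB = ikbkbGenotype)
    for (i in seq_along(.LOCI)) {
        locus <- .LOCI[i]
        if (is.na(geno[[locus]])) next
        sp <- species[[locus]][[geno[[locus]]]]
        helix <- rowSums(vapply(seq_len(nrow(sp)), function(k)
            sp$fraction[k] * .helicity(temp, sp$tm_c[k] + offset,
                                       sp$width_c[k]),
            numeric(length(temp))))
        sig <- sig + amps[i] * helix
    }
    MeltCurve(grid, sig + eps, "raw")
}

#' Cohort specifications
#'
#' `validationCohort()` reproduces the composition of the 46 dried-blood-spot
#' validation cohort: for ZAP70, 3 homozygous affected, 6 heterozygous and 1
#' homozygous normal; for IKBKB, 2 homozygous affected, 14 heterozygous and
#' 20 homozygous normal. Samples at risk for one locus are wild type at the
#' other. `controlCohort()` gives the unaffected control cohort (default 60
#' samples, wild type at both loci).
#'
#' @return A `data.frame` with columns `sample`, `zap70`, `ikbkb`,
#'   `risk_locus`, `role`.
#' @examples
#' nrow(validationCohort())   # 46
#' table(validationCohort()$ikbkb)
#' @export
validationCohort <- function() {
    block <- function(locus, genotype, n, tag) {
        other <- setdiff(.LOCI, locus)
        df <- data.frame(
            sample = sprintf("%s-%s-%02d", locus, tag, seq_len(n)),
            zap70 = "wild_type", ikbkb = "wild_type",
            risk_locus = locus, role = "unknown")
        df[[tolower(locus)]] <- genotype
        df
    }
    rbind(block("ZAP70", "homozygous_affected", 3, "HOM"),
          block("ZAP70", "heterozygous", 6, "HET"),
          block("ZAP70", "wild_type", 1, "WT"),
          block("IKBKB", "homozygous_affected", 2, "HOM"),
          block("IKBKB", "heterozygous", 14, "HET"),
          block("IKBKB", "wild_type", 20, "WT"))
}

#' @rdname validationCohort
#' @param n number of unaffected controls
#' @export
controlCohort <- function(n = 60) {
    data.frame(sample = sprintf("CTRL-%03d", seq_len(n)),
               zap70 = "wild_type", ikbkb = "wild_type",
               risk_locus = "none", role = "unknown")
}

## Default control block run on every plate: the caller is anchored on
## wild-type controls plus one het/hom control per locus, and one
## no-template well.
.controlBlock <- function() {
    data.frame(
        sample = c("WTCTRL-1", "WTCTRL-2", "WTCTRL-3",
                   "ZHETCTRL", "ZHOMCTRL", "IHETCTRL", "IHOMCTRL", "NTC"),
        zap70 = c("wild_type", "wild_type", "wild_type",
                  "heterozygous", "homozygous_affected",
                  "wild_type", "wild_type", NA),
        ikbkb = c("wild_type", "wild_type", "wild_type",
                  "wild_type", "wild_type",
                  "heterozygous", "homozygous_affected", NA),
        risk_locus = "none",
        role = c("control_wild_type", "control_wild_type",
                 "control_wild_type", "control_het_zap70",
                 "control_hom_zap70", "control_het_ikbkb",
                 "control_hom_ikbkb", "no_template"))
}

## A1..H12, then extended row letters (I.., AA..) for larger cohorts.
.wellNames <- function(n, ncolPlate = 12L) {
    rows <- ceiling(n / ncolPlate)
    rowNames <- c(LETTERS,
                  as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(rows)]
    paste0(rep(rowNames, each = ncolPlate),
           rep(seq_len(ncolPlate), rows))[seq_len(n)]
}

#' Simulate a plate for a cohort
#'
#' Simulates one well per cohort entry, prepending the standard control
#' block (three wild-type controls, one heterozygous and one homozygous
#' control per locus, one no-template well) unless the cohort already
#' carries control roles or `includeControls = FALSE`. Returns the plate,
#' the matching sample sheet, and the truth table for scoring.
#'
#' @param cohort `data.frame` with columns `sample`, `zap70`, `ikbkb` and
#'   optionally `role` and `risk_locus` (see [validationCohort()])
#' @param noise a [noiseModel()]
#' @param grid acquisition [TemperatureGrid-class]
#' @param seed integer seed; recorded in the plate metadata
#' @param config run configuration
#' @param includeControls prepend the standard control block
#' @return `list(plate = MeltPlate, sheet = data.frame, truth = data.frame)`;
#'   `truth` covers the cohort's `unknown`-role samples.
#' @export
simulatePlate <- function(cohort, noise = noiseModel(), grid = defaultGrid(),
                          seed = 1L, config = defaultRunConfig(),
                          includeControls = TRUE) {
    stopifnot(is.data.frame(cohort), nrow(cohort) > 0L,
              all(c("sample", "zap70", "ikbkb") %in% names(cohort)))
    cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
    if (is.null(cohort$role)) cohort$role <- "unknown"
    if (is.null(cohort$risk_locus)) cohort$risk_locus <- "none"
    if (anyDuplicated(cohort$sample))
        stop("validation error: duplicate sample identifiers in cohort")
    if (includeControls && !any(cohort$role != "unknown"))
        cohort <- rbind(.controlBlock(), cohort)
    cohort$zap70[cohort$role == "no_template"] <- NA
    cohort$ikbkb[cohort$role == "no_template"] <- NA

    species <- .speciesTables(config)
    wells <- .wellNames(nrow(cohort))
    signals <- .withSeed(seed, {
        vapply(seq_len(nrow(cohort)), function(i)
            curveSignal(simulateWell(cohort$zap70[i], cohort$ikbkb[i],
                                     grid, noise, config, species)),
            numeric(length(grid)))
    })
    colnames(signals) <- wells
    plate <- MeltPlate(grid, signals,
                       metadata = list(instrument = "scidHRM simulator",
                                       seed = seed,
                                       noise = unclass(noise)))
    sheet <- data.frame(well = wells, sample = cohort$sample,
                        role = cohort$role)
    truth <- cohort[cohort$role == "unknown",
                    c("sample", "zap70", "ikbkb", "risk_locus")]
    rownames(truth) <- NULL
    list(plate = plate, sheet = sheet, truth = truth)
}
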