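#' TemperatureGrid: the acquisition temperature axis
#'
#' Melt data are acquired on a uniform temperature grid; the instrument
#' protocol modelled here reads fluorescence between 75 and 95 degrees
#' Celsius in 0.2 degree increments (101 points). All curves on one plate
#' share a single grid, and every processing step validates against it.
#'
#' @slot points ordered acquisition temperatures in degrees Celsius
#' @slot tol uniformity tolerance in degrees Celsius
#' @export
setClass("TemperatureGrid",
         representation(points = "numeric", tol = "numeric"),
         prototype(points = numeric(), tol = 1e-6))

setValidity("TemperatureGrid", function(object) {
    p <- object@points
    if (length(p) < 2L)
        return("grid needs at least 2 points")
    if (any(!is.finite(p)))
        return("grid temperatures must be finite")
    d <- diff(p)
    if (any(d <= 0))
        return("grid temperatures must be strictly increasing")
    step <- stats::median(d)
    if (any(abs(d - step) > object@tol))
        return(sprintf(
            "grid is not uniform: step deviates from %.6g by more than %g",
            step, object@tol))
    TRUE
})

#' MeltCurve: one fluorescence trace on a temperature grid
#'
#' The atom of all processing: a single well's fluorescence signal, tagged
#' with its processing stage (`raw`, `smoothed`, `normalized` or `shifted`).
#' Normalized and shifted curves are helicity-scaled and bounded to
#' \[-0.05, 1.05\] (a small overshoot is tolerated from interpolation).
#'
#' @slot grid a [TemperatureGrid-class]
#' @slot signal relative fluorescence, one value per grid point
#' @slot stage processing stage
#' @export
setClass("MeltCurve",
         representation(grid = "TemperatureGrid", signal = "numeric",
                        stage = "character"))

setValidity("MeltCurve", function(object) {
    if (length(object@signal) != length(object@grid@points))
        return("signal length must equal grid length")
    if (length(object@stage) != 1L || !object@stage %in% .STAGES)
        return(sprintf("stage must be one of: %s",
                       paste(.STAGES, collapse = ", ")))
    if (object@stage %in% c("normalized", "shifted")) {
        s <- object@signal[is.finite(object@signal)]
        if (length(s) && (min(s) < -0.05 || max(s) > 1.05))
            return("normalized-stage signal must lie in [-0.05, 1.05]")
    }
    TRUE
})

#' DerivativeCurve: the negative first derivative of a melt curve
#'
#' Values are -d(RFU)/dT, so melt transitions appear as positive peaks whose
#' apex temperatures mark the amplicon melting temperatures.
#'
#' @slot grid a [TemperatureGrid-class]
#' @slot values -d(RFU)/dT at each grid point
#' @export
setClass("DerivativeCurve",
         representation(grid = "TemperatureGrid", values = "numeric"))

setValidity("DerivativeCurve", function(object) {
    if (length(object@values) != length(object@grid@points))
        return("values length must equal grid length")
    TRUE
})

#' DifferenceCurve: a shifted, normalized curve minus a reference
#'
#' The genotype classifier's input: pointwise difference between a
#' temperature-shifted normalized sample curve and the wild-type reference
#' of one amplicon domain.
#'
#' @slot grid the domain's [TemperatureGrid-class]
#' @slot values dimensionless differences, bounded by \[-1.05, 1.05\]
#' @slot locus `"ZAP70"` or `"IKBKB"`
#' @export
setClass("DifferenceCurve",
         representation(grid = "TemperatureGrid", values = "numeric",
                        locus = "character"))

setValidity("DifferenceCurve", function(object) {
    if (length(object@values) != length(object@grid@points))
        return("values length must equal grid length")
    v <- object@values[is.finite(object@values)]
    if (length(v) && max(abs(v)) > 1.05)
        return("difference values must be bounded by [-1.05, 1.05]")
    if (length(object@locus) != 1L || !object@locus %in% .LOCI)
        return("locus must be ZAP70 or IKBKB")
    TRUE
})

#' MeltPlate: a plate of melt curves sharing one grid
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass: rows are temperature points (with the temperature recorded in
#' `rowData`), columns are wells, and the single `"fluorescence"` assay
#' holds the traces. Well identifiers must be unique; they are free strings
#' so simulated cohorts of arbitrary size fit one plate.
#'
#' @export
setClass("MeltPlate", contains = "SummarizedExperiment")

setValidity("MeltPlate", function(object) {
    if (!"fluorescence" %in% SummarizedExperiment::assayNames(object))
        return("MeltPlate needs a 'fluorescence' assay")
    rd <- SummarizedExperiment::rowData(object)
    if (!"temperature" %in% colnames(rd))
        return("rowData must record the temperature grid")
    w <- colnames(object)
    if (is.null(w) || anyDuplicated(w))
        return("well identifiers must be present and unique")
    tg <- tryCatch(gridFromPoints(rd$temperature),
                   error = function(e) conditionMessage(e))
    if (is.character(tg)) return(tg)
    TRUE
})

#' MeltReference: control-anchored reference for genotype calling
#'
#' Holds, per locus, the wild-type reference curve (mean of the normalized,
#' thermally calibrated wild-type control wells), its half-melt temperature,
#' the genotype centroid difference curves learned from control wells, and
#' the within-control distance used to scale the outlier threshold. The
#' wild-type centroid is by construction the zero curve.
#'
#' @slot loci loci in ascending melt-temperature order
#' @slot domains per-locus temperature interval used for analysis
#' @slot windows per-locus pre/post-melt normalization windows
#' @slot bgSlope common plate-level background slope (RFU per degree
#'   Celsius) used to normalize every well; see [plateBackgroundSlope()]
#' @slot curves per-locus wild-type reference [MeltCurve-class]
#' @slot calTm matrix of reference calibration crossing temperatures
#'   (degrees Celsius), rows = calibration helicity levels, columns =
#'   loci
#' @slot centroids per-locus named list of genotype centroid
#'   [DifferenceCurve-class] objects
#' @slot tmDisplacement per-locus matrix of genotype crossing
#'   displacements relative to wild type (degrees Celsius), rows =
#'   calibration levels, columns = genotypes (`wild_type` column is 0)
#' @slot withinControl per-locus maximum wild-type control distance to zero
#' @slot controlWells wells used, by role
#' @slot excluded control wells excluded by QC, with reasons
#' @export
setClass("MeltReference",
         representation(loci = "character", domains = "list",
                        windows = "list", bgSlope = "numeric",
                        curves = "list", calTm = "matrix",
                        centroids = "list", tmDisplacement = "list",
                        withinControl = "numeric",
                        controlWells = "list", excluded = "character"))

#' ConcordanceSummary: accuracy of calls against known genotypes
#'
#' @slot nSamples scored (sample, locus) pairs
#' @slot nConcordant pairs where the call equals the truth (`no_call`
#'   always counts as discordant)
#' @slot accuracy `nConcordant / nSamples`
#' @slot perLocus accuracy by locus
#' @slot confusion per-locus truth-by-call count tables
#' @export
setClass("ConcordanceSummary",
         representation(nSamples = "integer", nConcordant = "integer",
                        accuracy = "numeric", perLocus = "numeric",
                        confusion = "list"))
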