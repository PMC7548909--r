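#' Construct a melt curve
#'
#' @param grid a [TemperatureGrid-class]
#' @param signal fluorescence values, one per grid point
#' @param stage processing stage: `"raw"`, `"smoothed"`, `"normalized"` or
#'   `"shifted"`
#' @return A [MeltCurve-class].
#' @export
MeltCurve <- function(grid, signal, stage = "raw") {
    new("MeltCurve", grid = grid, signal = as.numeric(signal), stage = stage)
}

#' Melt-curve accessors
#'
#' @param curve a [MeltCurve-class] (or [DerivativeCurve-class] /
#'   [DifferenceCurve-class] for `curveGrid()`)
#' @export
curveGrid <- function(curve) curve@grid

#' @rdname curveGrid
#' @export
curveSignal <- function(curve) curve@signal

#' @rdname curveGrid
#' @export
curveStage <- function(curve) curve@stage

#' @rdname curveGrid
#' @export
diffValues <- function(curve) curve@values

#' @rdname curveGrid
#' @export
diffLocus <- function(curve) curve@locus

#' Restrict a curve to a temperature interval
#'
#' Keeps the grid points with `tlow <= T <= thigh` (inclusive, with a small
#' numeric slack so window edges that coincide with grid points are kept).
#'
#' @param curve a [MeltCurve-class]
#' @param tlow,thigh interval bounds in degrees Celsius
#' @return A [MeltCurve-class] on the restricted grid.
#' @export
subsetCurve <- function(curve, tlow, thigh) {
    p <- gridPoints(curve@grid)
    keep <- p >= tlow - 1e-9 & p <= thigh + 1e-9
    if (sum(keep) < 3L)
        stop("subset error: fewer than 3 grid points in [",
             tlow, ", ", thigh, "]")
    MeltCurve(gridFromPoints(p[keep], curve@grid@tol),
              curve@signal[keep], curve@stage)
}

setMethod("show", "MeltCurve", function(object) {
    cat(sprintf("MeltCurve (%s): %d points, %.6g-%.6g C, signal range [%.4g, %.4g]\n",
                object@stage, length(object@grid),
                gridStart(object@grid), gridStop(object@grid),
                min(object@signal), max(object@signal)))
})

setMethod("show", "DerivativeCurve", function(object) {
    i <- which.max(object@values)
    cat(sprintf("DerivativeCurve: %d points, apex %.4g at %.2f C\n",
                length(object@grid), object@values[i],
                gridPoints(object@grid)[i]))
})

setMethod("show", "DifferenceCurve", function(object) {
    cat(sprintf("DifferenceCurve [%s]: %d points, max |diff| = %.4g\n",
                object@locus, length(object@grid), max(abs(object@values))))
})
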