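#' Construct a temperature grid
#'
#' `TemperatureGrid()` builds the acquisition grid from start, stop and step;
#' `gridFromPoints()` validates an observed temperature column (e.g. from a
#' plate export) against the uniform-grid contract; `defaultGrid()` is the
#' assay's 75-95 degrees Celsius, 0.2-degree protocol (101 points).
#'
#' @param start,stop,step grid limits and increment in degrees Celsius
#' @param tol uniformity tolerance in degrees Celsius
#' @return A [TemperatureGrid-class].
#' @examples
#' g <- defaultGrid()
#' length(gridPoints(g))   # 101
#' gridStep(g)
#' @export
TemperatureGrid <- function(start = 75, stop = 95, step = 0.2, tol = 1e-6) {
    stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
              step > 0, stop > start)
    n <- round((stop - start) / step)
    new("TemperatureGrid", points = start + step * (0:n), tol = tol)
}

#' @rdname TemperatureGrid
#' @param points numeric vector of observed temperatures
#' @export
gridFromPoints <- function(points, tol = 1e-6) {
    if (!is.numeric(points) || anyNA(points))
        stop("grid error: temperatures must be numeric and complete")
    g <- new("TemperatureGrid", points = as.numeric(points), tol = tol)
    v <- validObject(g, test = TRUE)
    if (is.character(v)) stop("grid error: ", v)
    g
}

#' @rdname TemperatureGrid
#' @export
defaultGrid <- function() TemperatureGrid(75, 95, 0.2)

#' Grid accessors
#'
#' @param grid a [TemperatureGrid-class]
#' @return `gridPoints()` the temperature vector; `gridStart()`,
#'   `gridStop()`, `gridStep()` scalars in degrees Celsius.
#' @export
gridPoints <- function(grid) grid@points

#' @rdname gridPoints
#' @export
gridStart <- function(grid) grid@points[1L]

#' @rdname gridPoints
#' @export
gridStop <- function(grid) grid@points[length(grid@points)]

#' @rdname gridPoints
#' @export
gridStep <- function(grid) stats::median(diff(grid@points))

setMethod("length", "TemperatureGrid", function(x) length(x@points))

setMethod("show", "TemperatureGrid", function(object) {
    cat(sprintf("TemperatureGrid: %.6g-%.6g C in steps of %.6g C (%d points)\n",
                gridStart(object), gridStop(object), gridStep(object),
                length(object)))
})

## Two grids are interchangeable when their points agree numerically.
sameGrid <- function(a, b, tol = 1e-9) {
    length(a@points) == length(b@points) &&
        max(abs(a@points - b@points)) <= tol
}
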