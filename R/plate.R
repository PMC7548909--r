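#' Construct a melt plate
#'
#' @param grid a [TemperatureGrid-class] shared by all wells
#' @param signals numeric matrix of fluorescence, rows = grid points,
#'   columns = wells (column names are the well identifiers)
#' @param metadata free-form key/value list (instrument, seed, ...)
#' @return A [MeltPlate-class].
#' @examples
#' g <- defaultGrid()
#' m <- cbind(A1 = seq(100, 5, length.out = length(g)),
#'            A2 = seq(90, 4, length.out = length(g)))
#' plate <- MeltPlate(g, m)
#' wellIds(plate)
#' @export
MeltPlate <- function(grid, signals, metadata = list()) {
    signals <- as.matrix(signals)
    if (nrow(signals) != length(grid))
        stop("format error: signal rows (", nrow(signals),
             ") do not match grid length (", length(grid), ")")
    if (is.null(colnames(signals)) || any(!nzchar(colnames(signals))))
        stop("format error: every well column needs a name")
    if (anyDuplicated(colnames(signals)))
        stop("format error: duplicate well identifiers: ",
             paste(unique(colnames(signals)[duplicated(colnames(signals))]),
                   collapse = ", "))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fluorescence = signals),
        rowData = S4Vectors::DataFrame(temperature = gridPoints(grid)),
        colData = S4Vectors::DataFrame(well = colnames(signals),
                                       row.names = colnames(signals)),
        metadata = metadata)
    new("MeltPlate", se)
}

#' Melt-plate accessors
#'
#' @param plate a [MeltPlate-class]
#' @return `meltGrid()` the shared [TemperatureGrid-class]; `wellIds()` the
#'   well identifiers; `plateSignals()` the fluorescence matrix;
#'   `wellCurve()` one well as a raw [MeltCurve-class].
#' @export
meltGrid <- function(plate) gridFromPoints(SummarizedExperiment::rowData(plate)$temperature)

#' @rdname meltGrid
#' @export
wellIds <- function(plate) colnames(plate)

#' @rdname meltGrid
#' @export
plateSignals <- function(plate) SummarizedExperiment::assay(plate, "fluorescence")

#' @rdname meltGrid
#' @param well a well identifier
#' @export
wellCurve <- function(plate, well) {
    if (!well %in% colnames(plate))
        stop("unknown well: ", well)
    MeltCurve(meltGrid(plate),
              SummarizedExperiment::assay(plate, "fluorescence")[, well],
              "raw")
}

setMethod("show", "MeltPlate", function(object) {
    g <- meltGrid(object)
    cat(sprintf("MeltPlate: %d wells on %.6g-%.6g C grid (%d points)\n",
                ncol(object), gridStart(g), gridStop(g), length(g)))
    md <- S4Vectors::metadata(object)
    if (length(md))
        cat("  metadata:", paste(names(md), collapse = ", "), "\n")
})
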