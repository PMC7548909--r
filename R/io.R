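#' Read a plate-format melt CSV
#'
#' Expects a comma-separated export with a header row: one column named
#' `Temperature` (case-insensitive) and one numeric column per well. The
#' temperature column must form a strictly increasing uniform grid (within
#' `tol`); the common qPCR acquisition protocol is 75-95 degrees Celsius in
#' 0.2-degree steps.
#'
#' @param path CSV file path
#' @param expectedGrid optional [TemperatureGrid-class]; when given, the
#'   file's grid must match it point for point
#' @param tol grid uniformity tolerance in degrees Celsius
#' @return A [MeltPlate-class].
#' @seealso [writeMeltPlate()]
#' @export
readMeltPlate <- function(path, expectedGrid = NULL, tol = 1e-6) {
    if (!file.exists(path)) stop("parse error: no such file: ", path)
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L)
        stop("parse error: need a temperature column and at least one well")
    tcol <- which(tolower(trimws(names(df))) == "temperature")
    if (length(tcol) != 1L)
        stop("parse error: exactly one 'Temperature' column required")
    temps <- suppressWarnings(as.numeric(df[[tcol]]))
    if (anyNA(temps))
        stop("parse error: non-numeric values in temperature column")
    wells <- names(df)[-tcol]
    if (anyDuplicated(wells))
        stop("format error: duplicate well column: ",
             paste(unique(wells[duplicated(wells)]), collapse = ", "))
    sig <- as.matrix(df[-tcol])
    storage.mode(sig) <- "double"
    if (anyNA(sig))
        stop("parse error: non-numeric fluorescence values")
    grid <- gridFromPoints(temps, tol)
    if (!is.null(expectedGrid) && !sameGrid(grid, expectedGrid, tol))
        stop("grid error: plate grid does not match the expected grid")
    MeltPlate(grid, sig, metadata = list(source = path))
}

#' Write a melt plate as CSV
#'
#' Inverse of [readMeltPlate()]: a `Temperature` column followed by one
#' column per well. Numeric values round-trip to better than 1e-9 relative.
#'
#' @param plate a [MeltPlate-class]
#' @param path output CSV path
#' @export
writeMeltPlate <- function(plate, path) {
    df <- data.frame(Temperature = gridPoints(meltGrid(plate)),
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(plateSignals(plate), check.names = FALSE))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a sample sheet
#'
#' A CSV with header `well,sample,role` mapping each well to a sample
#' identifier and its role on the plate. Roles must be one of
#' `r paste(sampleRoles(), collapse = ", ")`.
#'
#' @param path CSV file path
#' @return A `data.frame` with columns `well`, `sample`, `role`.
#' @export
readSampleSheet <- function(path) {
    if (!file.exists(path)) stop("validation error: no such file: ", path)
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("validation error: ",
                                            conditionMessage(e)))
    validateSampleSheet(df)
}

#' @rdname readSampleSheet
#' @param sheet a sample-sheet `data.frame` to validate
#' @export
validateSampleSheet <- function(sheet) {
    need <- c("well", "sample", "role")
    if (!is.data.frame(sheet) || !all(need %in% names(sheet)))
        stop("validation error: sample sheet needs columns well, sample, role")
    if (nrow(sheet) == 0L)
        stop("validation error: sample sheet is empty")
    sheet <- sheet[need]
    sheet[] <- lapply(sheet, as.character)
    bad <- setdiff(unique(sheet$role), .ROLES)
    if (length(bad))
        stop("validation error: unknown role(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(sheet$well))
        stop("validation error: duplicate well(s): ",
             paste(unique(sheet$well[duplicated(sheet$well)]), collapse = ", "))
    sheet
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
    utils::write.csv(validateSampleSheet(sheet), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

.validateCallReport <- function(report) {
    need <- c("well", "sample", "locus", "call", "confidence", "qc_flags")
    if (!is.data.frame(report) || !all(need %in% names(report)))
        stop("validation error: call report needs columns ",
             paste(need, collapse = ", "))
    report <- report[need]
    for (col in c("well", "sample", "locus", "call", "qc_flags"))
        report[[col]] <- as.character(report[[col]])
    report$confidence <- as.numeric(report$confidence)
    if (nrow(report)) {
        if (!all(report$locus %in% .LOCI))
            stop("validation error: locus must be one of ",
                 paste(.LOCI, collapse = ", "))
        if (!all(report$call %in% .CALLS))
            stop("validation error: unknown call value")
        if (any(!is.na(report$confidence) &
                (report$confidence < 0 | report$confidence > 1)))
            stop("validation error: confidence must lie in [0, 1]")
    }
    report
}

#' Write and read genotype call reports
#'
#' One row per (well, locus): `well, sample, locus, call, confidence,
#' qc_flags` (flags joined with `;`). Reports round-trip exactly through
#' both formats.
#'
#' @param report a call-report `data.frame` as produced by [callPlate()]
#' @param path output path
#' @param format `"csv"` or `"json"`
#' @export
writeCallReport <- function(report, path, format = c("csv", "json")) {
    format <- match.arg(format)
    report <- .validateCallReport(report)
    if (format == "csv") {
        utils::write.csv(report, path, row.names = FALSE)
    } else {
        jsonlite::write_json(report, path, dataframe = "rows",
                             digits = NA, auto_unbox = TRUE, pretty = TRUE)
    }
    invisible(path)
}

#' @rdname writeCallReport
#' @export
readCallReport <- function(path, format = c("csv", "json")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("I/O error: no such file: ", path)
    if (format == "csv") {
        df <- utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = c(well = "character",
                                             sample = "character",
                                             locus = "character",
                                             call = "character",
                                             confidence = "numeric",
                                             qc_flags = "character"))
    } else {
        df <- jsonlite::fromJSON(path)
        if (length(df) == 0L)
            df <- data.frame(well = character(), sample = character(),
                             locus = character(), call = character(),
                             confidence = numeric(), qc_flags = character())
    }
    if (nrow(df)) df$qc_flags[is.na(df$qc_flags)] <- ""
    .validateCallReport(df)
}
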