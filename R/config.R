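#' Run configuration
#'
#' Every tunable of the simulator, the curve-processing chain and the
#' genotype caller lives in one nested list, serializable to a flat
#' `key = value` text file (keys are dot-separated group/name pairs,
#' vector values comma-separated). `defaultRunConfig()` returns the
#' package defaults; `readRunConfig()` overlays a file on top of them.
#'
#' Groups:
#' \describe{
#'   \item{grid}{acquisition grid (`start`, `stop`, `step` in degrees C).}
#'   \item{thermo}{Tm convention: total strand `oligo_conc` (mol/L) and
#'     effective `monovalent` cation concentration (mol/L).}
#'   \item{sim}{simulator: nominal pre-melt `amplitude` (RFU, split evenly
#'     between the two amplicons), constant `baseline_rfu`, additive noise
#'     `rfu_sigma` (fraction of nominal amplitude), per-amplicon
#'     `amplitude_cv`, pre-melt background slope range
#'     (`baseline_slope_min`/`max`, RFU per degree C), per-well thermal
#'     calibration offset `temp_offset_sigma` (degrees C), heteroduplex
#'     destabilization `delta_zap70`/`delta_ikbkb` (degrees C), logistic
#'     transition `width` (degrees C).}
#'   \item{curve}{processing: Savitzky-Golay `smooth_window`/
#'     `smooth_polyorder`, peak thresholds `peak_min_prominence_frac` (of
#'     the global derivative maximum) and `peak_min_height` (absolute,
#'     -dRFU/dT), the default registration `shift_level` (helicity
#'     fraction) of [temperatureShift()], the thermal-calibration crossing
#'     `calibration_levels` (helicity levels 0.25, 0.40 and 0.70: all
#'     avoid a 50/50 heterozygote's half-melted plateau, and registering
#'     at two levels makes genotype displacement profiles distinguishable
#'     from a shared thermal offset) and the calibration cap `max_shift`
#'     (degrees C, a hard safety bound several standard deviations
#'     beyond the instrument's thermal offset spread).}
#'   \item{windows}{fixed per-locus pre/post-melt normalization cursors and
#'     whole-curve cursors, each `c(low, high)` in degrees C. A locus'
#'     analysis domain is the interval from its pre-window start to its
#'     post-window end.}
#'   \item{call}{classifier: `confidence_floor`, `outlier_multiplier` and
#'     `outlier_min` (distance units), minimum usable dynamic range
#'     `min_amplitude` (RFU), curve `metric` (`max_abs` or `rms`), and the
#'     `max_no_call_rate` tolerated by validation.}
#'   \item{loci}{the two loci in ascending melt-temperature order.}
#' }
#'
#' @return A nested named list.
#' @export
defaultRunConfig <- function() {
    list(
        grid = list(start = 75, stop = 95, step = 0.2),
        thermo = list(oligo_conc = 2e-7, monovalent = 0.11),
        sim = list(amplitude = 100, baseline_rfu = 5, rfu_sigma = 0.01,
                   amplitude_cv = 0.15, baseline_slope_min = -0.2,
                   baseline_slope_max = -0.05, temp_offset_sigma = 0.05,
                   delta_zap70 = -3, delta_ikbkb = -4, width = 0.35),
        curve = list(smooth_window = 7, smooth_polyorder = 3,
                     norm_smooth_window = 9,
                     peak_min_prominence_frac = 0.25, peak_min_height = 8,
                     shift_level = 0.05, max_shift = 0.35,
                     calibration_levels = c(0.25, 0.4, 0.7)),
        windows = list(zap70_pre = c(75.0, 76.8), zap70_post = c(83.2, 86.2),
                       ikbkb_pre = c(83.2, 86.2), ikbkb_post = c(93.2, 95.0),
                       whole_pre = c(75.5, 77.5), whole_post = c(93.0, 95.0)),
        call = list(confidence_floor = 0.7, outlier_multiplier = 3,
                    outlier_min = 0.1, min_amplitude = 10,
                    metric = "max_abs", max_no_call_rate = 0.01),
        loci = .LOCI)
}

.flattenConfig <- function(config, prefix = "") {
    out <- list()
    for (nm in names(config)) {
        key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
        val <- config[[nm]]
        if (is.list(val)) out <- c(out, .flattenConfig(val, key))
        else out[[key]] <- val
    }
    out
}

#' @rdname defaultRunConfig
#' @param config a configuration list
#' @param path text file of `key = value` lines
#' @export
writeRunConfig <- function(config, path) {
    flat <- .flattenConfig(config)
    fmt <- function(v) {
        if (is.numeric(v)) paste(formatC(v, digits = 15, format = "g"),
                                 collapse = ",")
        else paste(v, collapse = ",")
    }
    writeLines(sprintf("%s = %s", names(flat), vapply(flat, fmt, "")), path)
    invisible(path)
}

#' @rdname defaultRunConfig
#' @export
readRunConfig <- function(path = NULL) {
    config <- defaultRunConfig()
    if (is.null(path)) return(config)
    if (!file.exists(path)) stop("validation error: no such config: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    flatDefault <- .flattenConfig(config)
    for (line in lines) {
        kv <- strsplit(line, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2L)
            stop("validation error: bad config line: ", line)
        key <- trimws(kv[1L])
        valStr <- trimws(paste(kv[-1L], collapse = "="))
        parts <- trimws(strsplit(valStr, ",", fixed = TRUE)[[1]])
        ref <- flatDefault[[key]]
        val <- if (!is.null(ref) && is.numeric(ref)) as.numeric(parts)
               else {
                   num <- suppressWarnings(as.numeric(parts))
                   if (anyNA(num)) parts else num
               }
        keys <- strsplit(key, ".", fixed = TRUE)[[1]]
        config[[keys]] <- val
    }
    config
}

## Per-locus normalization windows and analysis domain from the config.
.locusWindows <- function(config, locus) {
    key <- tolower(locus)
    list(pre = config$windows[[paste0(key, "_pre")]],
         post = config$windows[[paste0(key, "_post")]])
}

.locusDomain <- function(config, locus) {
    w <- .locusWindows(config, locus)
    c(w$pre[1L], w$post[2L])
}

## the inter-window melt region: where genotypes are compared
.diffDomain <- function(config, locus) {
    w <- .locusWindows(config, locus)
    c(w$pre[2L], w$post[1L])
}
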