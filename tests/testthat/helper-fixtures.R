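# Fixtures built in code: logistic melt curves, plate CSVs, small cohorts.

logisticCurve <- function(grid = defaultGrid(), tm = 85, width = 0.35,
                          amplitude = 100, baseline = 5, slope = 0,
                          stage = "raw") {
    t <- gridPoints(grid)
    sig <- baseline + slope * (t - t[1]) +
        amplitude / (1 + exp((t - tm) / width))
    MeltCurve(grid, sig, stage)
}

# a normalized-scale logistic (1 -> 0), for shift/difference tests
unitLogistic <- function(grid = defaultGrid(), tm = 85, width = 0.35,
                         stage = "normalized") {
    t <- gridPoints(grid)
    MeltCurve(grid, 1 / (1 + exp((t - tm) / width)), stage)
}

writePlateCsv <- function(path, temps, wells) {
    df <- data.frame(Temperature = temps, check.names = FALSE)
    for (w in names(wells)) df[[w]] <- wells[[w]]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
}

defaultWindows <- function() meltWindows(c(75.5, 77.5), c(93, 95))

# small wt-only cohort used in several pipeline tests
tinyCohort <- function(n = 3) {
    data.frame(sample = sprintf("U%02d", seq_len(n)),
               zap70 = "wild_type", ikbkb = "wild_type",
               risk_locus = "none", role = "unknown")
}

mixedCohort <- function(n = 100) {
    pairs <- expand.grid(z = hrmGenotypes(), i = hrmGenotypes(),
                         stringsAsFactors = FALSE)
    idx <- rep(seq_len(nrow(pairs)), length.out = n)
    data.frame(sample = sprintf("S%03d", seq_len(n)),
               zap70 = pairs$z[idx], ikbkb = pairs$i[idx],
               risk_locus = "none", role = "unknown")
}

expectedCall <- function(report, truth) {
    mapply(function(s, l) truth[[tolower(l)]][match(s, truth$sample)],
           report$sample, report$locus)
}
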