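#' AmpliconModel: thermodynamic description of one assay amplicon
#'
#' Bundles an amplicon's wild-type sequence with its founder mutation so
#' that duplex species and their melting temperatures can be derived for
#' any genotype. The ZAP70 amplicon carries an intronic splice-site G>A
#' substitution (c.1624-11G>A); the IKBKB amplicon a single-G duplication
#' (c.1292dupG). The shipped sequences are synthetic fixtures: they begin
#' and end with the published assay primers but have synthetic interior
#' filler engineered so the two amplicons melt in well-separated domains of
#' the 75-95 degrees Celsius acquisition window; they make no claim of
#' genomic fidelity.
#'
#' @slot locus `"ZAP70"` or `"IKBKB"`
#' @slot wtSequence wild-type amplicon sequence
#' @slot mutationType `"substitution"` or `"duplication"`
#' @slot mutationPosition 1-based position of the mutated/duplicated base
#' @slot mutationAlt replacement base for substitutions
#' @export
setClass("AmpliconModel",
         representation(locus = "character", wtSequence = "DNAString",
                        mutationType = "character",
                        mutationPosition = "integer",
                        mutationAlt = "character"))

setValidity("AmpliconModel", function(object) {
    if (!object@locus %in% .LOCI) return("locus must be ZAP70 or IKBKB")
    if (length(object@wtSequence) >= 100L)
        return("amplicon must be shorter than 100 bases")
    if (!object@mutationType %in% c("substitution", "duplication"))
        return("mutationType must be substitution or duplication")
    p <- object@mutationPosition
    if (p < 2L || p > length(object@wtSequence) - 1L)
        return("mutation must be interior to the amplicon")
    TRUE
})

setMethod("show", "AmpliconModel", function(object) {
    cat(sprintf("AmpliconModel [%s]: %d bp, %s at position %d\n",
                object@locus, length(object@wtSequence),
                object@mutationType, object@mutationPosition))
})

#' Load the two assay amplicon models
#'
#' Reads the synthetic amplicon fixtures shipped with the package (FASTA,
#' with the mutation encoded in the header) and returns one
#' [AmpliconModel-class] per locus.
#'
#' @return Named list with elements `ZAP70` and `IKBKB`.
#' @examples
#' amps <- scidAmplicons()
#' ampliconTm(amps$ZAP70)                       # wild-type duplex Tm
#' ampliconTm(amps$ZAP70, mutant = TRUE)        # G>A destabilizes
#' @export
scidAmplicons <- function() {
    readOne <- function(locus) {
        path <- system.file("extdata",
                            sprintf("synthetic_amplicon_%s.fa", locus),
                            package = "scidHRM")
        set <- Biostrings::readDNAStringSet(path)
        hdr <- names(set)[1L]
        field <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", hdr)
        new("AmpliconModel", locus = locus, wtSequence = set[[1L]],
            mutationType = field("mutation"),
            mutationPosition = as.integer(field("position")),
            mutationAlt = if (grepl("alt=", hdr)) field("alt") else "")
    }
    list(ZAP70 = readOne("ZAP70"), IKBKB = readOne("IKBKB"))
}

#' Mutant amplicon sequence
#'
#' Applies the model's founder mutation to the wild-type sequence: a base
#' substitution for ZAP70, a single-base duplication (one base longer) for
#' IKBKB.
#'
#' @param model an [AmpliconModel-class]
#' @return A [Biostrings::DNAString-class].
#' @export
mutantSequence <- function(model) {
    b <- strsplit(as.character(model@wtSequence), "")[[1]]
    p <- model@mutationPosition
    if (model@mutationType == "substitution") {
        b[p] <- model@mutationAlt
    } else {
        b <- append(b, b[p], after = p)
    }
    Biostrings::DNAString(paste(b, collapse = ""))
}

#' @rdname mutantSequence
#' @param mutant compute the Tm of the mutant rather than wild-type duplex
#' @param params,oligoConc,monovalent passed to [primerTm()]
#' @export
ampliconTm <- function(model, mutant = FALSE, params = nnParameters(),
                       oligoConc = 2e-7, monovalent = 0.11) {
    seq <- if (mutant) mutantSequence(model) else model@wtSequence
    primerTm(as.character(seq), params, oligoConc, monovalent)
}

#' Duplex species present for a genotype
#'
#' After the final PCR denaturation/reannealing step, strands pair at
#' random. A homozygote therefore carries a single homoduplex; a
#' heterozygote reanneals into four species at mole fraction 0.25 each: the
#' two homoduplexes plus two mismatched/bulged heteroduplexes. Homoduplex
#' Tms are computed by nearest-neighbor thermodynamics on the wild-type and
#' mutant sequences; heteroduplex Tms are the homoduplex mean plus a
#' configurable destabilization (default -3 degrees Celsius for the ZAP70
#' single-base mismatch, -4 for the IKBKB single-base bulge).
#'
#' @param model an [AmpliconModel-class]
#' @param genotype `"wild_type"`, `"heterozygous"` or `"homozygous_affected"`
#' @param params nearest-neighbor parameters ([nnParameters()])
#' @param destabilizationDelta heteroduplex Tm offset in degrees Celsius
#'   (negative); default by locus as above
#' @param width logistic transition width in degrees Celsius
#' @param oligoConc,monovalent Tm convention, as in [primerTm()]
#' @return A `data.frame` with columns `label`, `tm_c`, `width_c`,
#'   `fraction`; fractions sum to 1.
#' @examples
#' amps <- scidAmplicons()
#' speciesForGenotype(amps$IKBKB, "heterozygous")
#' @export
speciesForGenotype <- function(model, genotype, params = nnParameters(),
                               destabilizationDelta = NULL, width = 0.35,
                               oligoConc = 2e-7, monovalent = 0.11) {
    if (length(genotype) != 1L || !genotype %in% .GENOTYPES)
        stop("validation error: unknown genotype: ", genotype)
    if (is.null(destabilizationDelta))
        destabilizationDelta <- if (model@locus == "ZAP70") -3 else -4
    tmWt <- ampliconTm(model, FALSE, params, oligoConc, monovalent)
    if (genotype == "wild_type")
        return(data.frame(label = "wt_homoduplex", tm_c = tmWt,
                          width_c = width, fraction = 1))
    tmMut <- ampliconTm(model, TRUE, params, oligoConc, monovalent)
    if (genotype == "homozygous_affected")
        return(data.frame(label = "mut_homoduplex", tm_c = tmMut,
                          width_c = width, fraction = 1))
    tmHet <- mean(c(tmWt, tmMut)) + destabilizationDelta
    data.frame(
        label = c("wt_homoduplex", "mut_homoduplex",
                  "heteroduplex_a", "heteroduplex_b"),
        tm_c = c(tmWt, tmMut, tmHet, tmHet),
        width_c = width, fraction = 0.25)
}
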