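Package: scidHRM
Title: High-Resolution Melt Genotyping of SCID Founder Mutations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Closed-tube high-resolution melting (HRM) analysis for the two
    founder mutations responsible for most TREC-negative severe combined
    immunodeficiency in Manitoba: ZAP70 c.1624-11G>A and IKBKB c.1292dupG.
    Provides a nearest-neighbor thermodynamic simulator for duplex melt
    curves of the two-amplicon multiplex assay (including heteroduplex
    species in heterozygotes and instrument noise), plate-format melt data
    input/output, the melt-curve analysis chain (Savitzky-Golay smoothing,
    negative first derivative, peak detection, per-amplicon normalization,
    temperature shifting and difference curves), and a control-anchored
    nearest-centroid genotype caller with confidence scores, no-call logic
    and concordance scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, Genetics, SNP, Preprocessing, Classification
RoxygenNote: 7.3.3
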