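Package: enuspectra
Title: Mutation-Spectrum Analysis and In Silico Saturation for ENU Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for the substitution spectrum of
    N-ethyl-N-nitrosourea (ENU) forward-genetics screens in the mouse.
    Classifies point mutations against transcript models into
    missense, nonsense, make-sense, splice and frameshift categories with
    overt-null flags; enumerates genome-wide substitution opportunities that
    alter coding sense or critical splice junctions and derives the binomial
    null for sense/antisense strand-asymmetry tests; computes exact binomial
    tail probabilities; enumerates the amino-acid change types reachable by
    single nucleotide substitutions; estimates the phenotypically detectable
    fraction of missense alleles from overt-null enrichment between
    phenotypic and incidental mutation sets; and simulates ENU mutagenesis
    in silico to estimate screen saturation. Ships toy-transcriptome and
    mutation-set generators plus packaged count tables so the whole pipeline
    is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
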