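Package: AcylRibo
Title: Quantification of Aminoacyl-tRNA Acetylation and Ribosome Pausing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two quantitative engines for studying toxins that acetylate the
    alpha-amino group of amino acids on charged tRNAs. The LC/MS engine does
    elemental-formula bookkeeping for the nuclease digestion products of
    (modified) aminoacyl-tRNAs, detects isobars, fits exponentially modified
    Gaussian peak models to extracted-ion chromatograms, and converts peak
    areas into acetylated fractions with relative-response-factor correction
    and delta-method uncertainty propagation. The ribosome-profiling engine
    computes 3'-end footprint density tracks, per-ORF pause scores, metagene
    A-site offset calibration, and mean pause score matrices for the A, P and
    E sites, localizing toxin-induced stalls to specific codons. A synthetic
    data generator produces ground-truthed chromatograms and footprint
    libraries over toy genomes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    minpack.lm,
    MASS,
    signal,
    pracma,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
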