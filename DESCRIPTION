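Package: sweepnet
Title: Selective Sweep Detection with Haplotype Statistics and a Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps from phased, polarized haplotype data.
    Implements five haplotype/site-frequency statistics that contrast variation
    on derived versus ancestral backgrounds (hapDAF-o, hapDAF-s, Sratio,
    lowfreq, highfreq) together with six established statistics (iHS, nSL,
    DIND, SAFE/iSAFE, HAF, H12 with an 80% identity threshold), assembles them
    into a normalized feature tensor over nested windows, and classifies loci
    as swept or neutral with a small convolutional neural network trained on
    simulations. Includes readers for ms-style simulator output and phased
    VCF with ancestral-allele polarization, a coalescent/Wright-Fisher fixture
    simulator, frequency-binned standardization against neutral simulations,
    and a genome-scan mode that merges sweep-classified window streaks into
    regions and estimates a false discovery rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    withr,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
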