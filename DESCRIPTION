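Package: duplexsc
Title: Duplex UMI Consensus Calling with Singleton Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Error suppression for duplex unique-molecular-identifier (UMI)
    sequencing libraries. Collapses PCR-duplicate read families into
    single-strand consensus sequences (SSCS), rescues singleton reads by
    comparison against the complementary strand of the same molecule
    (Singleton Correction, either against a complementary SSCS or a
    complementary singleton), forms duplex consensus sequences (DCS), and
    quantifies consensus efficiency, duplex recovery, and residual
    background error rates with 12-class substitution profiles. Includes an
    in-silico downsampler and a ground-truth read simulator so every stage
    can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    stringi,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    stats,
    methods,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
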