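Package: dalec
Title: Simulation and Analysis of DAM-Based Chromatin Accessibility Tag Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tissue-specific chromatin accessibility profiling based
    on bacterial DNA adenine methyltransferase (DAM) footprinting with
    asymmetric ligation end capture of GATC-flanking sequence tags. Builds and
    filters in-silico half-site tag databases from a genome, forward-simulates
    the molecular protocol (per-strand methylation, methylation-dependent
    restriction, type IIS tag release, linker ligation and read emission),
    parses and aligns raw reads to the tag database by exact match, computes
    control-normalised per-gene accessibility indices, divergence tests between
    samples, expression-score binning, and nucleosome dyad-anchored
    accessibility metaprofiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
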