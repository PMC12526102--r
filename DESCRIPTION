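Package: mtbreaks
Title: Strand-Break End Profiling and Turnover Kinetics for Circular
    Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps single- and double-strand breaks on circular mitochondrial
    genomes from long-read fragment-end data. Simulates fragment libraries
    from populations of circular genomes carrying strand-specific nicks and
    double-strand breaks (with restriction-enzyme linearization, optional S1
    nuclease conversion of nicks to double-strand breaks, and size
    selection), bins and depth-normalizes fragment-end frequencies, calls
    break hotspots by background-subtracted residual ranking with
    differential inference of single-strand breaks from paired native and
    S1-treated libraries, annotates called sites with GC-stretch and
    G-quadruplex motifs, and quantifies mtDNA turnover kinetics by
    exponential-decay fitting and four-parameter Chapman qPCR curve fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
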