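Package: yrscout
Title: Structural Annotation and Evolutionary Dynamics of Tyrosine-Recombinase Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating DIRS-order (tyrosine-recombinase) retrotransposons
    from consensus libraries and genome assemblies: detection of terminal-repeat
    architecture (inverted terminal repeats and internal complementary regions of
    DIRS-like elements; split direct repeats of Ngaro-like elements), ORF and
    conserved-domain scanning, homology-based copy retrieval and genome masking,
    divergence-based family clustering with majority-rule consensus building,
    CpG-adjusted Kimura 2-parameter divergence landscapes with age dating, and
    neighbor-joining distance trees with bootstrap support. Includes a synthetic
    data generator that plants element copies at known divergences in a background
    genome, so the whole pipeline is testable against machine-readable truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
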