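Package: minibar
Title: Sliding-Window Design and In Silico Validation of DNA Mini-Barcodes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates the shortest, most informative portion of a DNA-barcode
    alignment by a sliding-window scan under the Kimura 2-parameter model,
    validates the selected mini-barcode as a species-diagnostic marker
    (neighbor-joining tree congruence, Robinson-Foulds and K-score tree
    comparison, barcode-gap and Jeffries-Matusita separability analysis), and
    derives degenerate IUPAC primers from the conserved flanks of the winning
    window, evaluated by in-silico PCR. Includes a seeded generator of
    species-structured alignments with a planted hypervariable region so the
    whole workflow can be exercised without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
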