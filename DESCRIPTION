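Package: epimotif
Title: Stability Analysis of Epigenetically Modified i-Motif DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how epigenetic cytosine modifications
    (5-methyl-, 5-hydroxymethyl-, 5-formyl- and 5-carboxylcytosine) tune the
    stability of i-motif DNA. Implements van't Hoff analysis of UV melting
    curves recorded at 295 nm (first-derivative melting temperature,
    fraction-folded conversion, enthalpy and entropy of folding), sigmoid
    fitting of circular-dichroism pH titrations to obtain the transitional
    pH, processing and classification of CD and thermal difference spectra,
    and an in-silico screen that decomposes C-rich sequences into C-tracts
    and loops, overlays per-cytosine methylation calls from two cell lines,
    and summarizes differential and loop-adjacent methylation with a
    two-proportion test. A synthetic-data module generates melting curves,
    titrations, spectra and two-cell-line methylation tracks with known
    ground truth so every estimator can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    minpack.lm,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
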