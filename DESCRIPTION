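Package: LCRDesign
Title: Synthetic Gene Design and Ligase-Chain-Reaction Assembly Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs artificial genes for a given peptide and host organism and
    plans their assembly from short chemically synthesized oligonucleotides by
    ligase chain reaction under a slowly decreasing temperature. Couples
    codon-usage optimization (reverse translation against a host codon-usage
    table) with assembly-protocol planning in a single evolutionary search whose
    fitness combines codon-usage deviation, total nucleotide cost, and protocol
    complexity. Assembly correctness is judged by ordering all fragment-pair
    hybridization events by melting temperature, using a nearest-neighbor DNA
    thermodynamic model and a Zuker-style minimum-free-energy folding engine
    extended to strand pairs. Includes a Monte Carlo study of random three-strand
    mixtures and bundled oligo sets for a protease gene analogue.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
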