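Package: barbellr
Title: Barbell RNA Structures and Editing Inducer Element Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the "barbell" RNA secondary structures that
    flank site-selectively A-to-I edited adenosines: parsing and writing
    dot-bracket, CT and FASTA files, a deterministic base-pair maximisation
    folder, segmentation of pair tables into stems, bulges and internal loops
    under the ADAR helix-end rule, detection and measurement of editing
    inducer elements (EIEs) adjacent to edited stems, ortholog conservation
    analysis with compensatory-substitution classification, editing
    quantification from Sanger peak heights, reporter-construct coordinate
    operations (deletions and relocations), synthetic substrate generators,
    and a screening pipeline that tabulates EIE presence against editing
    efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
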