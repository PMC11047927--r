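Package: nanopanr
Title: Synthetic Nanobody Phage-Display Library Analysis and Binding Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing synthetic nanobody
    phage-display experiments: exact amino-acid statistics of
    degenerate-codon (NNB) randomised libraries, paired-end amplicon read
    processing with an intact-sequence filter, repertoire quality control
    (positional composition, occurrence spectrum, CDR3 length classes),
    positive/negative panning-pool specificity scoring for binder
    discovery, homolog-family clustering, three-parameter logistic
    dose-response fitting, global 1:1 biolayer-interferometry kinetics,
    sandwich epitope binning, and a fully seeded synthetic-data generator
    that emulates library assembly defects, sequencing, panning rounds,
    plate assays and sensorgrams with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
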