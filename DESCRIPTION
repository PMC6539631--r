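Package: popmtrigram
Title: Alignment-Free Protein Subcellular Localization via Property
    Tri-Gram Encoding and SVM-RFE
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein subcellular location from primary sequence
    alone.  Each residue is encoded as a 10-bit membership vector over
    Taylor's overlapping physicochemical groups, giving an L x 10 binary
    protein overlapping property matrix (POPM); sliding tri-gram products
    over adjacent rows yield a 1000-dimensional co-occurrence feature
    vector per protein.  Features are ranked by recursive feature
    elimination with a linear support vector machine (SVM-RFE), and a
    linear SVM classifier is evaluated by leave-one-out jackknife with
    per-class sensitivity, specificity, Matthews correlation coefficient,
    and overall accuracy.  Includes a synthetic sequence generator with
    class-dependent residue composition so the full pipeline is testable
    without external datasets, plus FASTA/TSV/CSV/JSON readers and writers
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
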