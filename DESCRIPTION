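Package: diffarch
Title: Differential Analysis of Two-Condition 3D Chromatin Architecture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the three-dimensional genome organization of
    two cell states from binned Hi-C contact matrices together with matched
    chromatin accessibility (ATAC-seq) tracks and expression tables. Implements
    iterative matrix correction (ICE), A/B compartment assignment from the
    first principal component of the observed/expected correlation matrix with
    two-condition switch classification, TAD insulation (separation) scoring
    with boundary calling and stable/gained/lost classification, chromatin
    loop detection by candidate selection, negative-binomial background
    testing and rank-sum peak/neighborhood comparison, aggregate peak analysis
    (APA) scoring, enhancer-promoter interaction calling with expression
    association, signal metaprofiles around genomic features including a
    detector for condensed accessibility dips flanking TAD boundaries, and a
    synthetic two-condition genome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
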