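Package: pksline
Title: Modular Type I Polyketide Synthase Annotation and Product Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates modular type I polyketide synthase (PKS) proteins at the
    catalytic-domain level by anchored active-site motif scanning, segments
    ordered domain hits into assembly-line modules across multiple proteins,
    classifies acyltransferase extender-unit specificity from GHSxG and
    secondary (HAFH/YASH/AAGH) motifs, and predicts the polyketide product on
    an explicit atom/bond graph: backbone carbon numbering, beta-carbon redox
    states, macrolactone and hemiketal rings, post-PKS tailoring, molecular
    formula and masses. Unusual extender units are reconciled against a target
    compound by candidate enumeration over side-chain lengths. Windowed
    GC-content profiling and module-count triage rank candidate biosynthetic
    gene clusters. A synthetic-cluster generator with planted motifs and
    regional GC structure makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
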