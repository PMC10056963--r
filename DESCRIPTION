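Package: sipgrowth
Title: Taxon-Specific Growth from 18O Quantitative Stable Isotope Probing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates taxon-specific microbial growth from 18O-water
    quantitative stable isotope probing (qSIP) experiments. Computes
    per-taxon weighted average buoyant densities from density-gradient
    fraction tables (qPCR totals plus per-fraction relative abundances),
    converts density shifts between paired 16O and 18O tubes into excess
    atom fraction (EAF) 18O estimates with block-bootstrap confidence
    intervals, and provides downstream treatment-response statistics
    (delta-EAF with bootstrap classification, occurrence partitions,
    van't Hoff Q10, rank-level aggregation), phylogenetic-signal tests
    (Blomberg's K with permutation p-values, Pagel's lambda with a
    likelihood-ratio test) implemented from first principles, and nested
    taxonomic variance components via random-intercept models. Includes a
    forward simulator of complete fractionated SIP experiments with known
    ground truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
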