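Package: altcbc
Title: Quantitative Analyses for Alternative Cap-Binding Complex Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of four quantitative procedures used to
    characterise the alternative nuclear cap-binding complex (NCBP1-NCBP3):
    permutation-FDR scoring of label-free AP-MS bait-versus-control intensity
    tables with an S0-moderated t-statistic; mask-based quantification of
    nuclear versus cytoplasmic poly(A) RNA FISH signal with one-way ANOVA and
    Tukey post-tests; pseudocount-based RIP-seq enrichment classification with
    an RNA-type breakdown; and dissociation-constant estimation from microscale
    thermophoresis dilution series via the exact 1:1 binding isotherm. Seeded
    synthetic-data generators with serialised ground truth accompany every
    stage, together with a configurable end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
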