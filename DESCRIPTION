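Package: vhlhet
Title: Quantifying Intratumoral VHL Heterogeneity from Genomic, Expression and Spatial Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify heterogeneity in VHL loss within clear cell renal
    cell carcinoma. Adjusts observed copy-number ratios and variant allele
    frequencies for tumor purity and ploidy assuming diploid normal
    contamination, applies sample- and variant-level filters, and classifies
    clonality of mutations and copy losses. Scores genes and gene sets for
    expression changes conserved across multiple VHL-loss comparisons with a
    signal-to-noise statistic, and profiles marker-labeled cell coordinates for
    boundary-relative infiltration and co-exclusion of cell phenotypes. Includes
    forward simulators for tumor-admixture cohorts, multi-comparison
    differential-expression studies, and two-region tissues, so every pipeline
    stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    seqinr
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
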