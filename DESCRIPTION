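Package: epicross
Title: Quantitative-Genetic Analysis of Binary Defect Phenotypes in Inbred Strain Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for case-control QTL studies of
    binary malformation phenotypes in F2 and advanced-intercross mouse
    cohorts carrying a heterozygous mutation. Provides a meiosis-level
    cross simulator with known genetic architecture, marker QC and
    genotype file input/output, three-state hidden Markov model genotype
    imputation with confidence summaries, genetic relatedness matrices
    with an F2 block override and nearest-positive-definite adjustment,
    binary-trait QTL scans with permutation thresholds, linear mixed
    model association and REML heritability with liability-scale
    transformation, physiological-epistasis decomposition of two-locus
    incidence tables into higher-order interaction effects, and
    syn-/anti-homozygous coadaptation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
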