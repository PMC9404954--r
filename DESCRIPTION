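Package: cercodent
Title: Genotype-Phenotype Mapped Dental Traits, Heritability and Ancestral
    State Reconstruction for Cercopithecid Monkeys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cercopithecid dental variation with
    genotype:phenotype-mapped crown traits. Computes molar module component
    (MMC), premolar-molar module (PMM), inhibitory-cascade (IC) ratios and
    two-dimensional crown areas from linear crown metrics; estimates
    pedigree-based heritability by maximum-likelihood variance decomposition
    with boundary-corrected likelihood-ratio tests; measures phylogenetic
    signal (Blomberg's K) and runs simulation-null phylogenetic ANOVA on a
    chronogram; reconstructs maximum-likelihood ancestral states under
    Brownian motion; and quantifies the discrepancy between ancestral state
    estimates and fossil trait values. Includes simulators for pedigrees,
    crown metrics and clade trait evolution so every stage can be validated
    against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    picante,
    e1071,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
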