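Package: synergyscreen
Title: Synergy Screening for 2x2 Factorial Mutant Expression Designs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects synergistic (non-additive) gene-expression changes in
    a four-genotype factorial design (wild type, two single mutants, and
    the double mutant), as used to dissect redundant gene function in
    Arabidopsis carpel margin meristem development. Provides per-gene
    one-way ANOVA fits with least-squares genotype means, the
    non-additivity (interaction) contrast against the additive
    expectation for the double mutant, Storey positive-false-discovery-rate
    q-values, two candidate-gene screens, pairwise cyclic loess
    normalization and probe-set summarization for array data,
    hypergeometric gene-family over-representation tests, and a qRT-PCR
    verification arm with delta-Ct quantification, reference-gene
    stability checks, and Tukey-Kramer HSD compact letter displays.
    Includes generators for synthetic factorial expression matrices,
    annotation universes, and Ct tables with known ground truth, plus a
    curated 31-gene candidate table from a published ATH1 screen of
    seu ant double-mutant gynoecia.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    limma,
    stats,
    utils
Suggests:
    multcomp,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
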