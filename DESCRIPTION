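Package: dsbquant
Title: Quantification Toolkit for CRISPR Double-Strand-Break Repair Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable quantification machinery for CRISPR double-strand-break
    repair studies: fragment-length (IDAA) editing-outcome quantification with
    Local Southern size calling, cell-cycle-resolved gamma-H2AX focus counting
    and micronucleus scoring from multi-channel fluorescence fields,
    Pearson colocalization, scratch-wound closure segmentation, flow-cytometry
    gating chains for transfection and homology-directed-repair readouts, and
    the accompanying statistical layer (group summaries, Student's t,
    one-way ANOVA with Tukey HSD, competitive-growth fitness). Every input
    modality has a seeded synthetic-data generator with known ground truth so
    each stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    zoo,
    MASS,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
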