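Package: coronaquant
Title: Quantitative Analysis of the Lipid Nanoparticle Protein Corona
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the protein corona that forms on lipid
    nanoparticles (LNPs) in biofluids and its downstream effect on cellular
    uptake. Covers density-gradient fraction quality control and selection
    from fluorescence profiles, Hi3 (top-3) label-free absolute protein
    quantification against a spiked internal standard, plasma-control
    normalized enrichment analysis with Benjamini-Hochberg correction,
    EASE-score over-representation of annotation terms, per-cell image
    quantification of uptake with erosion-based inner/outer membrane
    partitioning and lysosomal co-localization, nested and repeated-measures
    ANOVA with Dunnett many-to-one comparisons, and flow-cytometry gating
    summaries. A synthetic-data module generates every input with recorded
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    readr,
    tiff,
    mvtnorm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    car,
    withr,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
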