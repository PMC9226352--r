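Package: flexconcord
Title: Concordance Between AlphaFold2 Confidence Outputs and Protein
    Residue Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how the per-residue confidence outputs of
    AlphaFold2 structure models (pLDDT scores and predicted aligned error
    matrices) relate to residue flexibility measured from conformational
    ensembles. Implements distance-variation (DV) matrices as the
    interquartile range of C-alpha pair distances, root-mean-square
    fluctuation (RMSF) profiles with all-atom and domain-specific Kabsch
    superposition protocols including linker averaging, mass-weighted
    trajectory principal component analysis, dynamic cross-correlation
    matrices, AF2-score transforms of pLDDT, and per-residue and
    matrix-level concordance statistics (Pearson correlation, linear
    regression). A synthetic-ensemble generator with known ground truth
    (Gaussian chains, two-domain hinge motion, freely-jointed disordered
    chains, emulated pLDDT/PAE) makes every pipeline stage verifiable
    without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
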