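Package: mrpr
Title: Synthetic ChAP-Seq Peak Calling, Motif Discovery and Biophysical
    Model Fits for a Prophage Master Repressor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reproduce, on fully synthetic data with known ground
    truth, the computational analyses used to characterize a prophage master
    repressor: convolution-based ChAP-seq peak calling with a mean-subtracted
    Ricker (second-derivative-of-Gaussian) kernel and adaptive peak-width
    estimation, ZOOPS-EM position-weight-matrix motif discovery with
    automatic width selection and genome scanning, hydrogen/deuterium
    exchange (HDX-MS) peptide filtering and residue-level uptake assignment,
    and least-squares fits of the one-set-of-sites isothermal titration
    calorimetry isotherm and the Boltzmann thermal-unfolding sigmoid.
    Generators for every input (genome with planted operator sites, replicate
    coverage tracks, tiled HDX peptide tables, titration heats, melt curves)
    make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
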