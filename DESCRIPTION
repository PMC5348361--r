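Package: nmrpls
Title: Synthetic 1H-NMR Metabolomics Cohorts and OSC-PLS-DA Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale 1H-NMR metabolomics analysis pipeline: simulation of
    multi-group cohorts with known ground truth (Lorentzian lineshapes,
    dilution, jitter, noise), spectral bucketing with solvent-region
    exclusion, probability quotient normalization, Pareto scaling,
    orthogonal signal correction, NIPALS PLS-DA with repeated two-fold
    cross-validation and permutation testing, S-plot and correlation-colored
    loadings for variable selection, Benjamini-Hochberg-adjusted univariate
    fold-change tables, statistical total correlation spectroscopy (STOCSY)
    for peak annotation, and sparse-PLS metabolite-phenotype association
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
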