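Package: chromlip
Title: Standardized Chromatographic Lipophilicity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating octanol-water partition coefficients (log P)
    from reversed-phase thin-layer and high-performance liquid chromatography.
    Raw retention observables (TLC retardation factors, HPLC retention times)
    are transformed to the R_M and log k lipophilicity indices, extrapolated
    linearly to a fully aqueous mobile phase (R_MW, log k_W), and calibrated
    against reference standards of known log P to yield experimental log P
    estimates for test compounds. Includes chemometric comparison of
    lipophilicity scales (correlation matrices, pairwise regression
    diagnostics, hierarchical clustering with Newick export, principal
    component analysis), lipophilic ligand efficiency (pIC50 - log P), and a
    seeded synthetic retention-data generator for validating the full pipeline
    by parameter recovery. Ships the published lipophilicity and pharmacology
    tables for five gliflozin (SGLT-inhibitor) antidiabetic drugs as example
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
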