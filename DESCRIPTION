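Package: lfer2p
Title: Two-Parameter Linear Free Energy Relationships for Protein and
    Lipid Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-water and lipid-water partition coefficients
    of neutral organic chemicals from their octanol-water (log Kow) and
    air-water (log Kaw) partition coefficients using two-parameter linear
    free energy relationships (2p-LFERs), alongside classical one-parameter
    and Abraham-descriptor poly-parameter models. Provides ordinary
    least-squares calibration with bootstrap coefficient uncertainty and
    backward term elimination, a validation toolbox (hold-out, k-fold and
    repeated k-fold cross-validation, leave-one-out, bootstrap validation,
    Bland-Altman agreement), chemical-space diagnostics (standardized PCA
    with square cosines, Pearson correlation matrices, Williams-plot
    applicability domain), a multiphase equilibrium partitioning model for
    mammalian tissue, plasma and milk distribution, and a seeded synthetic
    chemical-table generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
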