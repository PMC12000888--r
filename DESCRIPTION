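Package: fdomlink
Title: Linking Fluorescent Dissolved Organic Matter to Bacterial Community
    Structure and Assembly
Version: 0.1.0
Authors@R:
    person("Caohai", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline connecting excitation-emission matrix
    (EEM) fluorescence spectroscopy of dissolved organic matter to
    16S-based bacterial community analysis. Provides EEM preprocessing
    (blank subtraction, inner-filter correction, Raman normalization,
    scatter excision, wavelength trimming), nonnegative PARAFAC
    decomposition with split-half validation and component classification,
    CDOM optical indices (FI, BIX, HIX, SUVA254, spectral slopes and
    slope ratio), alpha/beta diversity and NMDS ordination, betaMNTD/betaNTI
    phylogenetic null models of community assembly, Sloan neutral community
    model fitting, Spearman co-occurrence networks with topology metrics,
    DOM-community linkage statistics, and synthetic-data generators with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
Config/testthat/parallel: false
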