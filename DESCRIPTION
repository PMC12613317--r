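Package: AuNPScore
Title: Descriptor-Based Scoring of Small-Molecule Binding to
    Monolayer-Protected Gold Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts binding free energies (kcal/mol) of small organic
    analytes to thiolate-monolayer-protected gold nanoparticles from five
    molecular descriptors: ligand and analyte Crippen logP, the absolute
    ligand-analyte net-charge difference at pH 7.4, and Tanimoto
    similarities of ligand and analyte to fixed reference scaffolds.
    Provides the frozen published linear scoring function, the full ridge
    regression training and validation protocol (standardization, nested
    repeated k-fold cross-validation with alpha grid search, variance
    inflation factors), Tanimoto-based hierarchical clustering of ligand
    and analyte chemistries, and a synthetic dataset generator for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
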