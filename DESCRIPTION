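Package: sitevar
Title: Superposition and Conformational Variation Analysis of Enzyme
    Active Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs enzyme active sites from multi-chain structures
    using catalytic-residue annotations, superposes homologous sites over
    functional atom triads with a symmetry-aware Gaussian-weighted Kabsch
    fit, annotates and classifies nearby ligands by a maximum-common-
    substructure chemical similarity score, and characterises per-family
    conformational behaviour (inherently rigid, inherently flexible,
    open/closed, extensively variable). A synthetic fixture generator
    produces structures, annotations and conformer ensembles with known
    ground truth so the whole pipeline runs and tests without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    mclust,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
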