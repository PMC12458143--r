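Package: lassomf
Title: Non-Covalent Lasso Entanglements and Protein Misfolding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects non-covalent lasso entanglements (NCLEs) in protein
    structures via partial Gauss linking integrals, calls significant
    proteinase-K cut-sites from limited-proteolysis mass-spectrometry peptide
    tables, and links the two with odds-ratio, propensity-matching and
    permutation statistics. Also provides an L1-regularised logistic
    classifier of protein essentiality from NCLE topology features, order
    parameters (fraction of native contacts Q and entanglement-change
    fraction G) for classifying misfolded trajectory frames and their
    loss/gain mechanisms, and seeded synthetic-data generators with recorded
    ground truth for every input class the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
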