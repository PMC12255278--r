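Package: sgchem
Title: Steroidal Glycoside Chemodiversity from Untargeted LC-MS and qPCR Count Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies steroidal glycoside (SG) chemodiversity from untargeted
    LC-MS data of Solanum leaf chemotypes. Implements monoisotopic mass
    arithmetic for glycosyl residues (fragment-ladder prediction, elemental
    formula assignment, glycan decomposition), neutral-loss mass-difference
    networking with retention-time-corrected adjacency, extracted-ion-
    chromatogram chemotyping, a glycosylation-signature census of SGs per
    steroidal aglycone species, chemodiversity indices (Margalef richness,
    Pielou evenness), variation partitioning of SG counts by Poisson GLM
    ANOVA-simultaneous component analysis with permutation validation, a
    count-based qPCR expression model with reference-gene soft normalization,
    and multivariate ordination (PCA, PCoA, PERMANOVA). Ships a synthetic-data
    generator emulating two leaf chemotypes across organs and ontogeny with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
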