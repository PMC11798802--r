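Package: ph4ensemble
Title: Ensemble Pharmacophore Models with Majority-Vote Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds structure-based pharmacophore models from conformational
    ensembles of a protein binding site. Pharmacophore features (donor,
    acceptor, charged, aromatic, hydrophobic spheres) are perceived per
    conformation, clustered into frequency-annotated consensus features,
    binarized into a conformation-by-feature occurrence matrix, and ranked
    against a binding/non-binding frame label by four statistics (ANOVA F,
    mutual information, recurrence-plot diagonal-line entropy, and absolute
    Spearman correlation); features selected by all four methods form the
    pharmacophore query. Queries screen multi-conformer ligand libraries by
    minimum-RMSD rigid matching of annotation points, and screening
    performance is summarized as a hit-ratio enrichment factor. Includes a
    seeded synthetic-data generator so the whole pipeline runs and validates
    without external structures or compound databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
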