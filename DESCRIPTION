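Package: pfcbiogeo
Title: Protein Functional Clusters from Sequence Similarity Networks and
    Their Environmental Biogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sequence similarity networks from pairwise protein
    alignment hits, extracts protein functional clusters (PFCs) as
    connected components, scores their functional and taxonomic
    homogeneity and flags "dark" clusters lacking any annotation,
    normalizes per-gene read counts into length- and depth-corrected
    abundances, curates environmental tables (near-zero-variance and
    correlation filtering, scaling, k-nearest-neighbour imputation),
    screens cluster abundances against environmental predictors with
    repeated cross-validated random-forest regression, and ordinates
    the environment-linked clusters with constrained correspondence
    analysis including permutation tests and stepwise variable
    selection.  Ships a synthetic-data generator with planted ground
    truth so the whole chain is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    caret,
    vegan,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
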