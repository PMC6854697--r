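Package: reposim
Title: Similarity-Fusion Drug Repositioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for predicting new disease indications for existing
    drugs by guilt-by-association scoring over fused similarity matrices.
    Drug features (SMILES chemical structure, target-protein and enzyme
    amino-acid sequences, differential gene-expression profiles reduced by a
    stacked auto-encoder) and disease features (phenotype and genotype term
    annotations reduced by PCA) are encoded into continuous vectors,
    per-feature cosine similarity matrices are fused by min-max
    normalisation into drug-drug (DDSI) and disease-disease (DiDiS)
    similarity matrices, and every drug-disease pair is scored by the
    maximum geometric mean of its similarities to a known association.
    Includes seeded synthetic-cohort generators, leave-one-out and
    cross-validated AUC evaluation protocols, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
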