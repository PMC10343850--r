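Package: cascadeMDA
Title: miRNA-Disease Association Prediction with a Cascade Forest and
    Stacked Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a bipartite
    association network. Disease similarity is computed from an ontology DAG
    with two semantic-contribution schemes and combined with Gaussian
    interaction-profile (GIP) kernel similarity; miRNA functional similarity
    is integrated with its GIP kernel the same way. Each miRNA-disease pair
    is represented by concatenated similarity and interaction-profile rows,
    compressed with a greedy stacked autoencoder, and scored by a cascade
    forest whose levels stack out-of-fold class probabilities from four
    diverse tree ensembles, with a polynomial-kernel SVM as the final
    predictor. Includes synthetic generators (random ontology forests,
    planted low-rank association matrices, latent-factor functional
    similarity), the split/cross-validation evaluation protocol, and a
    leave-one-disease-out case-study ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ranger,
    xgboost,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
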