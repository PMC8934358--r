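Package: dtbanet
Title: Drug-Target Binding Affinity Regression over Weighted Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts continuous drug-target binding affinities (pKd, KIBA
    scores) without protein 3D structure. Builds a weighted heterogeneous
    graph from drug-drug similarity, target-target similarity and transformed
    affinity edges; extracts meta-path sum/max score features via (plus,times)
    and (max,times) semiring matrix products with simple-path corrections;
    derives sequence embeddings (3-gram skip-gram protein vectors, pluggable
    SMILES encoders); fits gradient-boosted regression trees; and evaluates
    with MSE, concordance index, rm2, thresholded AUPR and Y-randomization
    under nested cross-validation and time-based splits. Includes a seeded
    latent-factor synthetic data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
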