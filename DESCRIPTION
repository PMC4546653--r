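Package: eegrsa
Title: Representational Similarity Analysis from Multi-Class EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-trial EEG decoding and representational similarity
    analysis. Implements multi-class linear discriminant classification of
    trial-space EEG matrices with ten-fold cross-validation and nested
    selection of the number of principal components, derivation of
    representational dissimilarity matrices from normalized multi-class
    confusion matrices (self-normalization, geometric-mean symmetrization,
    distance extraction), classical multidimensional scaling and UPGMA
    hierarchical clustering of the resulting distances, spatially and
    temporally resolved searchlight decoding, and exact binomial inference
    on classifier accuracy. A synthetic trial-space data generator with a
    planted category hierarchy makes the whole pipeline testable without
    access to recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
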