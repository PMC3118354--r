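Package: conformap
Title: Two-Level Conformational Analysis of Molecular Dynamics Ensembles
    with Self-Organising Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups and compares conformational ensembles of protein domains
    with a two-level strategy: Essential Dynamics (PCA) filtering of Calpha
    coordinates, an optimised Self-Organising Map (SOM) that summarises the
    ensemble into prototype vectors, and hierarchical post-clustering of the
    prototypes with Mojena's stopping rule. Includes a Taguchi experimental
    design protocol with stepwise regression to optimise SOM hyperparameters,
    a Cressie-Read goodness-of-fit test to validate trajectory sampling rates,
    GROMOS nearest-neighbour clustering and Silhouette / Davies-Bouldin
    indices for baseline comparison, and a synthetic-ensemble generator with
    planted conformational basins for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
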