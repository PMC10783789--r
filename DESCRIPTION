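Package: copingmanifold
Title: Stability of Prefrontal Population Dynamics During Threat Coping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium imaging recorded while
    mice alternate between active (struggle) and passive (immobility) coping
    under tail-suspension threat. Provides per-neuron context-selectivity and
    movement-tuning scores with circular-shift surrogate significance,
    balanced cross-validated decoding of behavioral context, coping style and
    speed (within and across conditions and days), low-dimensional manifold
    embedding (isomap, PCA, spectral) with epoch-averaged template manifolds,
    orthogonal Procrustes alignment across days and individuals with
    random-rotation and shuffle nulls, and a synthetic multi-animal,
    multi-day session generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    e1071,
    igraph,
    FNN,
    rhdf5,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
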