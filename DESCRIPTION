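Package: cortexlrp
Title: Explainable CNN Classification of Cortical Current-Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for explainable classification of
    event-related cortical current-density maps. Generates synthetic single-trial
    source-space activity for a patient/control working-memory study design,
    reduces trials to a critical 150-250 ms window, flattens each cortical
    hemisphere to a square raster with the equal-area Mollweide projection,
    trains a compact VGG-style convolutional network under leave-one-subject-out
    cross-validation with class balancing and early stopping, attributes the
    classifier's decisions to cortical vertices with composite layer-wise
    relevance propagation (LRP-0, LRP-epsilon, LRP-gamma), extracts top-relevance
    critical regions, and correlates their activity with clinical scores by
    Spearman rank correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
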