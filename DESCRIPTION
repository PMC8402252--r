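Package: ataxgait
Title: Ataxic Gait Classification from Motion-Capture Joint Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for classifying ataxic versus healthy gait from
    3-D motion-capture joint trajectories. Provides a seeded synthetic gait
    generator with a controllable severity parameter and exact ground truth,
    turn and foot-contact detection with straight-segment extraction, six
    clinically motivated gait features (cadence, step length, step trajectory,
    relative step length, centre-of-mass sway, and two spectral band
    energies), feature scaling and class balancing (including SMOTE),
    two-dimensional embedding by PCA, t-SNE and UMAP, a ten-classifier
    evaluation grid under 60/40 holdout and leave-one-group-out
    cross-validation, and severity-separation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    e1071,
    class,
    rpart,
    randomForest,
    nnet,
    Rtsne,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
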