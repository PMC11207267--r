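Package: flightclass
Title: Feature Selection and Cascade Classification of Flight Tracks from
    Stereovision Bird-Protection Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying flying objects (aeroplanes, large raptors,
    other birds) from long-baseline stereovision flight trajectories recorded
    around wind turbines. Converts raw two-camera pixel tracks to spherical
    trajectories, extracts a 78-variable motion/size feature scheme (angular
    velocity histograms, distance-binned averages, variances), selects
    features with a Pearson correlation filter and a wrapper genetic
    algorithm driven by a threshold-penalised accuracy/recall fitness, tunes
    decision thresholds for recall-critical imbalanced classification, and
    runs a two-stage cascade (aeroplane vs bird, then big raptor vs other
    bird). Includes a synthetic trajectory simulator with straight, soaring
    and flapping motion archetypes for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    rpart,
    nnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
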