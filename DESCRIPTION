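Package: neurorbit
Title: Mixed Sensorimotor Selectivity and Orbital Neural Geometry in Motor
    Cortex Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how target motion modulates reach-direction coding in
    motor cortex populations during flexible manual interception. Provides
    simulation of cosine-tuned model neurons with sigmoidal velocity modulation
    of gain, preferred direction and offset; statistical classification of
    single-unit modulation (Watson-Williams and signed-rank criteria) and
    nonlinear tuning-model fits compared by adjusted R-squared; PCA neural-state
    geometry with per-condition 3D ellipse fits and tilt/rotation/shift metrics;
    sliding-window and cross-condition population decoding with linear support
    vector machines; and a task-trained rate recurrent network (rectified-tanh
    units, backpropagation through time with Adam) whose node population
    reproduces the orbital neural-state geometry, with ablation, connection
    scaling, connectivity and latent-dynamics comparison analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
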