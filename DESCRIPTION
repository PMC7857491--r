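Package: efqo
Title: Quantitative Analysis of Fluorescence-Quenched Oligonucleotide
    Exonuclease Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of end-labeled fluorescence-quenched
    oligonucleotide (EFQO) acid 5'-exonuclease assays from 96-well
    plate-reader kinetic exports: baseline and control-drift correction,
    calibration of fluorescence to moles of hydrolyzed substrate,
    initial-rate and integrated activity, Michaelis-Menten and
    four-parameter-logistic dose-response fitting (IC50), pH-optimum and
    thermal-midpoint profile estimation, and group statistics (fold
    changes, one-way ANOVA with Dunnett's many-to-one comparison).
    Includes a seeded progress-curve simulator of whole plates so every
    stage can be validated against generative ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    multcomp,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
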