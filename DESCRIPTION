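Package: mixlfl
Title: Mixture QSPR Models for Lower Flammability Limits of Binary
    Hydrocarbon Gases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative structure-property relationship (QSPR) modelling of
    the lower flammability limit (LFL, vol%) of binary hydrocarbon gas
    mixtures. Computes the molecular descriptors of the published
    six-parameter model (rotatable-bond count, maximal electrotopological
    positive variation, intrinsic-state pseudoconnectivity, Burden-matrix
    eigenvalues, 3D-MoRSE signals) from SMILES via a deterministic
    distance-geometry embedding; combines pure-component descriptors into
    mixture descriptors by twelve mixing rules; selects descriptor subsets by
    genetic-algorithm multiple linear regression; and validates models by
    leave-one-out Q2, points-out external splits, Y-randomization and a
    leverage-based applicability domain (Williams plot). Ships a frozen
    published model and a synthetic binary-mixture generator built on Le
    Chatelier's rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
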