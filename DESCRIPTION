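Package: xtalgnn
Title: Graph Neural Networks for Molecular Crystal Density Prediction and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for molecular crystal structure prediction support built
    around a 12-parameter crystal representation with a deterministic unit-cell
    and supercell builder, two synthetic fake-crystal generators (multivariate
    Gaussian sampling of reduced lattice parameters and controlled distortion
    of existing crystals), a periodic molecular-crystal graph convolution, and
    two small graph neural networks: a density model predicting the crystal
    packing coefficient from a single rigid conformer, and a discriminator
    scoring whole crystal structures as real versus generated. Includes the
    associated scoring functions (softmax stretch score, van der Waals overlap
    score, quantile filtering), a minimal CIF reader and writer, a deterministic
    synthetic fixture generator, and desk-scale training and evaluation
    pipelines implemented in base R with a compact reverse-mode autodiff tape.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
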