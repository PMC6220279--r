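Package: stereophantom
Title: Design-Based Stereology and Brain Morphometry on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end replica of a design-based neuroanatomical analysis
    chain exercised on synthetic brain phantoms with known ground truth.
    Provides Cavalieri volume estimation with 2D-nucleator section areas,
    optical-fractionator and disector-density cell counting with
    Gundersen-Jensen coefficient-of-error accounting, label-volume regional
    morphometry with Laplace-equation cortical thickness and pointwise group
    t-maps, Fisher-exact cell-type enrichment of differentially expressed
    gene lists with Benjamini-Hochberg correction, and qPCR standard-curve
    quantification with reference-gene stability ranking. A phantom-cohort
    generator produces two-genotype cohorts, cellular point patterns, serial
    histological sections, marker gene-set collections and qPCR plates that
    statistically emulate a real study design, so every estimator can be
    validated against analytic or generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    car,
    fgsea
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
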