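Package: rdctensor
Title: Alignment Tensor Analysis of Residual Dipolar Couplings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of one-bond residual dipolar couplings
    (RDCs) of small molecules in weakly aligning media. Extracts RDCs from
    scalar and total couplings with error propagation, fits Saupe order
    matrices to rigid conformers by error-weighted singular value
    decomposition (single-conformer-single-tensor, SCST), fits one common
    tensor to population-weighted conformer ensembles superposed in an
    Eckart frame (multi-conformer-single-tensor, MCST) with exhaustive
    population scanning, computes Cornilescu quality factors, compares
    alignment tensors through the generalized five-dimensional angle used
    for enantiodifferentiation, and handles Boltzmann conformer-population
    bookkeeping. A synthetic-data generator produces structures, tensors
    and coupling tables with the statistical structure the analysis
    assumes, so the whole pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'molio.R'
    'couplings.R'
    'saupe.R'
    'ensemble.R'
    'compare.R'
    'populations.R'
    'synthetic.R'
    'report.R'
    'cli.R'
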