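Package: carbopk
Title: Carboplatin AUC-Targeted Dosing Algorithms and Sparse-Sampling
    Pharmacokinetic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute carboplatin doses under the Calvert formula with
    an adjusted Cockcroft-Gault algorithm (adjusted ideal body weight for
    overweight patients, a serum-creatinine floor, and a creatinine-clearance
    cap) and nine comparator renal-function estimators; to simulate synthetic
    patient cohorts with a latent true carboplatin clearance; to simulate and
    fit sparse ultrafiltrate concentration data under a two-compartment
    infusion model with maximum a posteriori (empirical Bayes) estimation of
    individual clearance; and to evaluate each dosing method's bias and
    precision (MPE%, MAPE%) against the target exposure, stratified by body
    mass index category.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
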