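Package: mlcqa
Title: Simulated Sensitivity of IMRT/VMAT Dose and Patient-Specific QA to
    MLC Leaf-Tip Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico study of how the multileaf-collimator (MLC)
    leaf-tip model of a treatment planning system (leaf-tip offset, leaf-tip
    width, transmission) perturbs calculated dose for modulated radiotherapy
    plans, and whether patient-specific QA based on gamma analysis of a
    diode-array measurement can detect such modeling errors.  Provides a
    double-step leaf-tip transmission model, a convolution-kernel planar
    dose engine with a virtual cylindrical head-and-neck phantom, a
    synthetic generator for step-and-shoot IMRT and VMAT plan suites, a
    global-gamma-index implementation with a brute-force oracle, tie-aware
    ROC/AUC analysis, and a study runner that reproduces the full
    perturbation-grid experiment with deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
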