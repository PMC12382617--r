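Package: ebikin
Title: Dose-Response Kinetics of Antibiotic Degradation Under Electron-Beam Irradiation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the degradation of antibiotics and the formation and decay of
    their transformation products in aqueous solutions treated with accelerated
    electrons. Provides a closed-form first-order kinetic model in absorbed dose
    with a threshold-dose (Heaviside-onset) law for degradation products,
    nonlinear least-squares parameter estimation from LC-MS peak-area dose
    series, reconstruction of the initial contamination level from
    degradation-marker signals, Fricke ferrous-sulfate dosimetry with linear
    charge-to-dose calibration, removal-percentage statistics with two-factor
    ANOVA and Tukey comparisons, a curated ledger of DFT-derived bond
    dissociation energies and degradation pathways for marker ranking, and a
    synthetic peak-table generator emulating triplicate HPLC-HRMS measurements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
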