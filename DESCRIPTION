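Package: quantpk
Title: Calibration, Validation Statistics and Non-Compartmental
    Pharmacokinetics for LC-MS/MS Bioanalysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative chain of an LC-MS/MS bioanalytical
    assay and its downstream pharmacokinetic application: calibration-curve
    fitting with the Wagner log-log quadratic model and back-calculation of
    concentrations from instrument responses; regulatory method-validation
    statistics (accuracy and precision, absolute recovery, internal-standard
    normalized matrix factors, stability panels, cross-matrix validation);
    non-compartmental pharmacokinetic analysis of blood concentration-time
    profiles (terminal slope, trapezoidal AUC, clearance and volumes) and
    dose-normalized oral bioavailability; and a ground-truthed synthetic-data
    generator for peak-area batches and one-compartment blood kinetics so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
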