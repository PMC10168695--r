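Package: polyblock
Title: Simulation and Analysis of Voltage-Dependent Polyamine Block of
    AMPA Receptor Currents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying voltage-dependent block of calcium-permeable
    AMPA-type glutamate receptor (CP-AMPAR) currents by intracellular
    polyamines and polyamine toxins such as NASPM. Provides a kinetic
    simulator of open-channel block (with optional blocker permeation and
    trapping) that generates voltage-ramp, fast-application, paired-pulse and
    miniature EPSC recordings; a ramp analysis pipeline with leak
    subtraction, rectification indices, conductance-voltage construction and
    single or double Boltzmann fitting with IC50 at 0 mV potency estimation;
    exponential decay and paired-pulse recovery kinetics with weighted time
    constants; threshold-crossing mEPSC detection with a frequency-weighted
    rectification index; and estimation statistics (Welch t-tests, mean
    differences with bias-corrected and accelerated bootstrap intervals).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
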