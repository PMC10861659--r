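Package: trichoScreen
Title: Hair Detectability of Prohibited Substances: Disposition Simulation,
    Semi-Quantitation, Incorporation Degrees and QSAR Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying which doping agents deposit from blood into
    growing hair. Simulates multi-matrix drug disposition in a repeated
    oral-dose rodent design (plasma kinetics, interval excretion into urine
    and faeces, AUC-proportional hair deposition, and an LC-MS-like
    response/censoring model), performs matrix-matched calibration with
    signal-to-noise based limits of detection, computes plasma AUC and hair
    incorporation degrees with group summaries and cross-matrix detection
    grids, and screens substance lists for hair detectability with a
    descriptor-based random-forest classifier bounded by a range-based
    applicability domain. Ships the 17-compound doping-control model panel
    with hair/plasma detection labels and a segmental human-hair report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    ChemmineR,
    ChemmineOB,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
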