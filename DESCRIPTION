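Package: cariesim
Title: Markov Microsimulation of Proximal Caries Detection and Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tooth-level Markov Monte-Carlo microsimulation of proximal caries
    detection on bitewing radiographs with versus without AI assistance, and of
    the downstream restorative, endodontic and prosthetic care cascade over a
    lifetime horizon. Simulates annual cycles from age 12 with age-dependent
    lesion development and progression hazards, stage-specific test accuracies,
    micro-invasive (resin infiltration) versus restorative management of
    detected lesions, and the full failure cascade from composite restoration
    through crowns, root canal treatment and retreatment to extraction and
    implant-supported replacement. Provides probabilistic sensitivity analysis,
    incremental cost-effectiveness ratios, cost-effectiveness plane quadrant
    statistics, acceptability curves and a univariate sensitivity table, all
    driven by plain-JSON parameter and fee-schedule configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
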