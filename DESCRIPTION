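Package: atroprop
Title: Cortical Atrophy Progression Mapping with Connectome and Receptor
    Colocalization Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing regional cortical atrophy progression in
    ageing and Alzheimer's disease cohorts from parcellated longitudinal
    morphometry tables. Provides normative W-score maps relative to a
    control group, region-wise linear mixed-effects progression maps
    (group-by-age interaction) with false-discovery-rate control,
    variogram-matched surrogate maps for spatially constrained
    significance testing of map-to-map correlations, a structural
    connectome neighbor-spread statistic with group-consensus connectome
    construction, receptor and transporter colocalization, and methods
    for comparing dependent and independent correlations (Fisher z and
    Zou confidence intervals). Includes a synthetic cohort generator
    with known ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
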