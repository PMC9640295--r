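Package: abpmvar
Title: Reproducibility and Variability of Sequential Ambulatory Blood
    Pressure Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the reproducibility of repeated
    ambulatory blood pressure monitoring (ABPM) sessions and pulse wave
    velocity measurements. Summarizes raw cuff readings into diary-defined
    day/night/24-h session means, classifies nocturnal dipping, estimates
    the within-individual coefficient of variation by the Bland-Altman
    logarithmic method with confidence intervals, screens study arms for
    stability with repeated-measures ANOVA, models determinants of blood
    pressure variability with standardized-coefficient regression, and
    measures multi-session dipping agreement with Fleiss' kappa. Includes
    a hierarchical lognormal cohort simulator emulating the measurement
    structure of sequential ABPM trials for validation and power work.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
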