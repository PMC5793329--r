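Package: fopsim
Title: Simulating Processed-Food Replacement Under Front-of-Package
    Nutrient Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the effect of front-of-package (FOP)
    nutrition-labeling criteria on population nutrient intake. Processed
    foods in 24-hour dietary recall data are classified against
    configurable category-specific nutrient-profiling criteria sets,
    non-compliant foods are replaced by compliant foods of the same
    category (optionally rescaling amounts by the ratio of energy
    densities so that energy intake is conserved), and changes in energy
    and nutrient intake between scenarios are summarized with
    survey-weighted medians, interquartile ranges, percent changes, and
    cluster-robust contrasts on log-transformed intake. A synthetic-data
    generator with analytically known ground truth supports end-to-end
    validation of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lmtest,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
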