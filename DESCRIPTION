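Package: mhei
Title: Metric Healthy Eating Index-2015 Scoring Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing the metric Healthy Eating Index-2015
    (mHEI-2015) and the original HEI-2015 from weighed dietary records.
    Implements a five-digit food coding system, gram-equivalent conversion
    based on energy-density change through processing, recipe decomposition
    of multi-ingredient menu items, the 13-component diet-quality scorer
    (adequacy, moderation and fatty-acid components per 1000 kcal), the
    calibration procedure that derives metric scoring standards from paired
    imperial/metric consumption data, and Bland-Altman agreement analysis
    for comparing two indices on the same cohort. A synthetic-data module
    generates food databases, recipes and intake cohorts with controllable
    dietary patterns so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    ggplot2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
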