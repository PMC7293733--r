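Package: fgfratlas
Title: Pan-Cancer FGF/FGFR Expression Biomarker Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tumor-versus-normal differential expression screening,
    optimal-cutpoint survival association, expression-drug-sensitivity
    association on cell-line panels, and prevalence-calibrated biomarker
    positivity prediction for the FGF/FGFR gene families across cancer
    cohorts. Includes a synthetic-data generator that emulates TCGA-like
    pan-cancer cohorts and GDSC-like cell-line panels with planted,
    known effects, so every analysis stage can be validated against a
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
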