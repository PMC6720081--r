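Package: dtadesign
Title: Classification of Test Accuracy Study Designs for Systematic Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine that classifies test accuracy studies from
    structured metadata into the four basic epidemiological designs
    (diagnostic cohort-type cross-sectional, diagnostic case-control-type
    cross-sectional, prognostic cohort, prognostic case-control), driven by
    a pre-specified dual time-interval policy separating diagnostic from
    prognostic/predictive questions. Includes a design-aware 2x2 accuracy
    measure calculator that withholds predictive values and apparent
    prevalence under case-control sampling, risk-of-bias pre-screening
    flags (delayed verification, lead time, sampling quality), worked
    example study records, and seeded synthetic participant generators for
    cohort and matched case-control sampling schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
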