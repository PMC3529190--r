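Package: searisk
Title: Absolute Invasive Breast-Cancer Risk Projection for South-East
    Asian Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gail-type 5-year absolute risk projection of invasive breast
    cancer under competing mortality, adapted to Singaporean women of
    Chinese, Malay and Indian origin. Ships the published age-specific
    incidence and competing-mortality rate tables, the BCDDP, GAIL-SBSP,
    S-GAIL-SBSP and E-GAIL-SBSP coefficient sets with their
    attributable-risk adjustments, risk-factor category coding, the
    piecewise-constant competing-risks projection engine, calibration
    (expected/observed ratios, chi-square goodness of fit, decile tables)
    and discrimination (weighted age-specific concordance) machinery, and
    a seeded piecewise-exponential cohort simulator that serves as a
    Monte-Carlo oracle and screening-cohort stand-in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
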