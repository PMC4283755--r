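Package: seamsel
Title: Treatment Selection for Two-Stage Seamless Phase II/III Trials with
    an Early Endpoint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis tools for two-stage adaptive seamless phase
    II/III clinical trials in which several experimental treatments are
    compared with a control and one treatment is selected at an interim
    analysis using a rapidly observable early endpoint alongside partially
    observed final-endpoint data. Implements three interim selection rules
    (early-endpoint-only, efficient-score combining early and final data,
    and a data-driven rule that chooses between them using plug-in selection
    probabilities), analytic selection and joint-agreement probabilities via
    multivariate normal integration, the familywise-error-controlling
    confirmatory analysis (Dunnett intersection tests, weighted inverse-normal
    combination, closed testing), and a Monte-Carlo engine for operating
    characteristics under a bivariate-normal endpoint model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mvtnorm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
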