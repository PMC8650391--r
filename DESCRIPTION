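Package: latentresp
Title: Latent-Variable Analysis of Composite Responder Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of composite responder endpoints built from one or two
    continuous components and an optional binary component, as used in
    rheumatology trials (e.g. SRI-type endpoints in systemic lupus
    erythematosus).  Implements the standard collapse-to-binary analysis and
    an augmented analysis that jointly models the components with a latent
    Gaussian model, retaining the information in the continuous measures.
    Provides per-arm response probabilities, odds-ratio, risk-ratio and
    risk-difference effects with delta-method or bootstrap confidence
    intervals, goodness-of-fit diagnostics, a power and sample-size
    calculator driven by pilot estimates, a synthetic trial generator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
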