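Package: surgchoice
Title: Patient Choice of Surgeon from Online Ratings and Report Cards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how publicly reported quality information
    shapes patient choice of cardiac surgeon.  Provides a synthetic market
    generator with evolving online review streams and report-card issues,
    linkage of both information sources to surgeon-by-quarter states,
    geographic choice-set construction with fixed- and variable-radius
    market definitions, a random-coefficient (mixed) logit estimator with
    surgeon fixed effects fitted by simulated maximum likelihood on Halton
    draws, a Gauss-Hermite quadrature oracle for the likelihood, and
    post-estimation statistics: heterogeneity shares, willingness to
    travel, bootstrap average marginal effects, and year-trend interaction
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    yaml,
    pracma,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
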