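Package: crsim
Title: Similarity Testing for Parametric Competing Risks Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equivalence (similarity) testing for two-group parametric
    competing risks models. The test statistic is the maximum over event
    states of the sup-norm distance between cause-specific transition
    intensities on a fixed time window, and the reference distribution is
    obtained by a constrained parametric bootstrap that regenerates data
    from maximum-likelihood estimates re-fitted under the null boundary
    constraint. Supports exponential, Gompertz and Weibull intensities,
    administrative and random right-censoring, maximum-likelihood and
    constrained maximum-likelihood estimation, an event-history simulator,
    a per-transition intersection-union comparator, a data-adaptive minimal
    similarity threshold, and a Monte Carlo study driver for operating
    characteristics (Type I error and power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
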