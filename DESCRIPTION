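Package: ctelm
Title: Continuous-Time Bayesian Eye-Movement Models of Visual Search
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulators and fitting tools for a family of Bayesian ideal-observer
    models of multi-saccade visual search: the entropy-limit-minimization (ELM)
    searcher with fixed 250-ms fixations, its continuous-time extension (CTELM)
    in which a leaky drift-diffusion evidence process and a collapsing decision
    bound determine saccade timing, and a constrained variant (CCTELM) that adds
    a saccade-amplitude penalty, eccentricity-dependent saccade landing noise,
    and a limited memory of past fixations. Includes the supporting visibility-map
    psychophysics (Weibull psychometric fits, d-prime conversion, spatiotemporal
    visibility-field fitting), eye-movement summary statistics with
    Bhattacharyya-coefficient goodness of fit, a genetic-algorithm fit of the
    saccade-timing parameters, a memory-capacity sweep, synthetic-data
    generators for every fitting path, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
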