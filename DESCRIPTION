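Package: hospsfa
Title: Bayesian Stochastic Frontier Analysis of Hospital Cost Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates translog cost frontiers for hospital panels by Gibbs
    sampling, under a common-coefficient (homogeneity) specification and a
    hierarchical random-coefficient (heterogeneity) specification with
    hospital-specific slopes drawn from a multivariate normal population.
    Inefficiency enters as a half-normal composed-error term sampled by
    truncated-normal data augmentation; cost efficiency is scored as the
    posterior mean of exp(-u). Includes panel preparation (CPI deflation,
    case-mix weighting, linear-homogeneity normalization), a synthetic
    hospital-panel generator with known ground truth for validation,
    efficiency and bias reporting, kernel density export of inefficiency,
    and single-chain convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
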