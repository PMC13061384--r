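Package: planmix
Title: Loewe Concentration-Addition Analysis of Binary Pesticide Mixtures
    in Planarian Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse multi-readout concentration-response screening
    data from binary chemical mixtures under the Loewe concentration-addition
    (CA) null model. Estimates per-readout benchmark concentrations (BMCs)
    with bootstrap confidence limits against readout-specific benchmark
    responses, fits fixed-asymptote log-logistic inhibition curves (IC50,
    Hill slope), predicts mixture BMCs and ICp values for arbitrary mixing
    fractions from single-agent potencies, classifies mixture interactions
    as additive, synergistic or antagonistic by confidence-interval
    comparison, and implements the logit-equivalence slope test of
    concentration additivity for acetylcholinesterase inhibition. Includes a
    synthetic generator for planarian-style high-throughput behavioral
    screens with known ground truth so that every stage is testable without
    experimental data.
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
    yaml,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
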