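Package: chronoHGT
Title: Horizontal Gene Transfer Constraints on Molecular-Clock Posteriors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of Bayesian relaxed-molecular-clock posteriors
    using relative-age constraints from horizontal gene transfers (HGTs).
    Reads datedist-style samples of dated, ultrametric chronograms, resolves
    named crown and total (stem-inclusive) group ages, scores every sampled
    chronogram against donor-older-than-recipient HGT constraints, uses the
    resulting compatibility percentages as an empirical model-selection
    criterion and as a posterior filter, and recomputes node-age summaries
    (means and equal-tailed credible intervals) from the constraint-compatible
    subsample. Includes a fixed-topology Yule simulator of posterior samples
    with planted HGT constraints so the whole pipeline can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
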