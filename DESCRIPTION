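Package: sexselmeta
Title: Multilevel Meta-Analysis of Sexual Selection Experimental Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesising experimental evolution studies that
    manipulate the strength of sexual selection and measure fitness
    components. Computes standardised effect sizes (Hedges' g from group
    summaries or test statistics, log response ratio, log coefficient of
    variation ratio, log variability ratio) with their sampling variances,
    fits multilevel random-effects meta-regressions by restricted maximum
    likelihood with moderators, linear contrasts and per-level predictions,
    partitions heterogeneity across random-effect levels (multilevel I2),
    and provides publication-bias diagnostics (Egger regression, funnel
    export, time-lag and impact-factor trend regressions). A synthetic-data
    generator produces hierarchical, moderated, heteroscedastic effect-size
    datasets with known ground truth so every stage of the pipeline can be
    validated by simulation.
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
    metafor,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
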