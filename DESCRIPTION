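Package: gxesim
Title: Simulating and Detecting Gene-Environment Interaction with Twin,
    Polygenic Score and Genome-Wide Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates twin-family genotype and phenotype data under a
    moderated polygenic model and detects gene-environment interaction (GxE)
    on the same data with three approaches: per-SNP moderated-regression
    genome-wide scans with Wald tests, polygenic-score-by-environment
    regressions built from discovery summary statistics, and a moderated ACE
    twin variance-components model fit by full-information maximum
    likelihood. Includes Monte Carlo power and sample-size analysis for main
    versus interaction effects, and runners that orchestrate complete
    simulation studies from generation through all three analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
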