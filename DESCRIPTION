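Package: motorlab
Title: Single-Molecule Analysis of the Phage T4 DNA Packaging Motor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative single-molecule analysis of viral genome
    packaging by ring-ATPase motors, built around the bacteriophage T4
    terminase (gp17). Implements binomial stoichiometry inference from
    photobleaching step counts (with a nonlinear forward-backward filter and
    penalized changepoint step detection), hetero-pentamer coordination
    activity models, censored exponential-mixture analysis of DNA-engagement
    kinetics, optical-trap packaging-trace analysis (worm-like-chain tether
    screening, rolling-window velocity, pause detection and pause-free
    velocity), and a Gillespie kinetic Monte Carlo simulator of DNA
    translocation with slipping. Ships synthetic-data generators with recorded
    ground truth so every analysis stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
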