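Package: symcycle
Title: Evolution of Symbionts Through Serial Host-Entry Bottlenecks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how a selective bottleneck at host entry shapes
    the adaptation of horizontally transmitted bacterial symbionts. Provides
    a stochastic two-trait life-cycle simulator (nodulation competitiveness
    and within-host proliferation, with rhizosphere hypermutagenesis and a
    single-founder nodulation bottleneck), cohort analysis of whole-population
    allele-frequency trajectories, a gene-level parallelism statistic (G
    score) with a length-weighted multinomial randomization null, competitive
    index statistics for co-inoculation assays, and ground-truthed synthetic
    data generators so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
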