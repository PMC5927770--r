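Package: quantalr
Title: Quantal Analysis of Synaptic Transmission at the Drosophila NMJ
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tidyverse-native tools for quantal analysis of neuromuscular
    junction electrophysiology: detection of spontaneous miniature events and
    evoked response amplitudes from raw sweeps, quantal content and
    presynaptic homeostatic potentiation (PHP) assessment, readily releasable
    pool (RRP) estimation by back-extrapolation of cumulative EPSC amplitudes
    during high-frequency trains, and variance-mean (multiple-probability
    fluctuation) analysis to estimate quantal size and the number of
    functional release sites.  Includes a binomial-release synthetic-data
    generator with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
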