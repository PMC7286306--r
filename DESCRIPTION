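Package: energyscape
Title: Energy Landscape Analysis of Oscillatory Brain Network States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum entropy (Ising) models to binarized
    band-limited oscillatory activity of brain network regions, characterizes
    the resulting energy landscape (local minima, basins of attraction,
    disconnectivity graphs), simulates network dynamics with the
    Metropolis-Hastings algorithm, tests local minima against a
    parameter-shuffling permutation null, and classifies participants by
    leave-one-out support vector machines on relative-energy features. Includes
    a synthetic-cohort generator with ground-truth models and planted group
    effects so every stage of the pipeline is verifiable without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
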