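Package: culturenet
Title: Network Activity Analysis for Cultured Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous activity of cultured neuronal
    networks recorded on multielectrode arrays (MEA) and by calcium imaging.
    Detects and classifies network bursts from the total spiking rate in 50-ms
    bins, infers delayed-synchrony functional connectivity (the proportion of
    transmitted spikes per ordered electrode pair, maximised over a grid of
    axonal delays), selects the strongest 5 percent of connections, identifies
    hub electrodes and reconstructs the functional graph. Detects calcium
    transients in dF/F traces and summarises the percentage of active cells,
    event rate and event duration. Includes a synthetic-recording generator
    with planted hub networks and planted calcium event statistics, with
    presets for sham, amyloid-beta, BDNF-treated and 5xFAD culture conditions,
    so every stage of the pipeline is verifiable by parameter recovery.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
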