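Package: oscbalance
Title: Event-Synchronization Effective Networks and the Oscillation-Balance
    Index for Multichannel Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds time-resolved directed weighted effective networks from
    multichannel intracranial-EEG-like recordings by event synchronization
    and event directionality of local-maximum event trains, decomposes the
    resulting asymmetric adjacency matrices into complex eigenmode layers,
    and summarises each snapshot by the balance between slow global and
    strong local oscillatory deformation (the H_sb index). Includes
    phase-wise kernel-density dynamics of the balance index, peak-tracking
    plunge statistics across seizure phases, scoped sub-network analyses,
    a fully seeded synthetic SEEG generator with ground-truth events and
    couplings, and minimal EDF and delimited-text readers.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
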