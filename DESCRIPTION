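Package: zfcipn
Title: Neuromuscular Junction Colocalization and Larval Behaviour
    Quantification for Zebrafish Neuropathy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies neuromuscular junction integrity and
    stimulus-avoidance behaviour in zebrafish larvae, the readouts used in
    chemotherapy-induced peripheral neuropathy models. Confocal two-channel
    stacks (presynaptic SYT2, postsynaptic acetylcholine receptor) are
    reduced to maximum-intensity projections, thresholded per channel with
    the Kapur maximum-entropy method, masked, and summarized as Manders
    M1/M2 and Pearson colocalization coefficients plus 8-connected particle
    metrics. Larval position tracks from a moving-bar plate assay yield the
    percent-down avoidance statistic and per-larva swim speed. Group
    comparisons use modified Thompson tau outlier rejection and pooled
    two-sample t-tests. Ground-truthed simulators for both data types
    support parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
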