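Package: pbstime
Title: Beam Delivery Time and Spot Sequence Modeling for Pulsed
    Synchrocyclotron Proton Pencil Beam Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the beam delivery time (BDT) and spot delivery sequence of
    a compact superconducting synchrocyclotron proton pencil-beam-scanning
    system that delivers each energy layer through several radiation bursts.
    Implements the four-component decomposition of delivery time (energy layer
    switching, burst switching, spot switching, spot spill), serpentine scan
    ordering with shortest-route line entry, three-burst pulse allocation from
    a maximum-efficiency model, 1 kHz delivery-log emission and parsing,
    re-calibration of every machine parameter from log-style observations, and
    a rigid-phantom interplay-effect simulator comparing burst and non-burst
    delivery under periodic respiratory motion and volumetric repainting.
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
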