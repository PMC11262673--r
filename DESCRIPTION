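Package: mtrecon
Title: Monitored Tomographic Reconstruction Protocols for Computed Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for planning and simulating monitored tomographic
    reconstruction (MTR) protocols, in which computed-tomography images are
    reconstructed in real time from partial projection data so that
    acquisition can be stopped early. Provides projection acquisition-order
    generators (consecutive, random, logarithmic) with angular travel
    metrics; per-projection scan time and dose models with presets for
    micro, nano, medical, cargo and electron-beam CT instruments; a GPU
    reconstruction-cost model for batch and incremental filtered back
    projection and iterative methods; a 2D parallel-beam tomography core
    with phantom generation, ramp filtering, batch and O(1) incremental
    partial FBP, and SIRT; and a discrete-event simulator of the
    asynchronous monitored acquisition loop with pluggable stopping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
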