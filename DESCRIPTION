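Package: tfbp
Title: Coupled Transcription-Factor Branching Processes on Cistromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation and mean-field analysis of transcription
    factor branching processes (TFBPs) over cistromes, the genome-wide sets of
    DNA segments bound by a transcription factor. Each producing segment that
    is active at a timestep emits m TF units that land uniformly over the
    cistrome's segments, activating producing segments and being absorbed by
    the rest; segments shared between cistromes couple them by transferring
    TFs across. The package provides a fast compiled engine for single and
    coupled cistrome systems (parameterised directly from ChIP-seq-derived
    segment counts or from BED interval lists), closed-form infinite-limit
    critical branching values for single and coupled cistromes, and experiment
    drivers that estimate critical branching parameters, ignition of
    dissipated cistromes, and the reduction of critical values under coupling,
    as studied for the mouse embryonic stem cell pluripotency factors Nanog,
    Oct4, Sox2 and cMyc.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
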