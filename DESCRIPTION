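Package: ipqms
Title: Bait-Normalized IP-QMS Interactome Analysis of SWI/SNF Complexes
Version: 0.1.0
Authors@R:
    person("Malte", "Verner", email = "malte.verner@posteo.net", role = c("aut", "cre"))
Description: Analysis pipeline for affinity-purification quantitative mass
    spectrometry (IP-QMS) experiments on chromatin remodeling complexes:
    IgG-background filtering, bait (BRG1) normalization, Welch/BH differential
    enrichment between immunoprecipitations, SWI/SNF (BAF) subtype composition
    summaries, multi-evidence transcription-factor classification, and
    single-cell SWI/SNF co-expression independence testing. Ships a versioned
    29-gene SWI/SNF subunit catalog and synthetic-data generators with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
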