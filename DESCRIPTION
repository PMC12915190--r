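Package: photomics
Title: Dual-Channel Fiber-Photometry Analysis and Omics Differential-Expression Screening
Version: 0.1.0
Authors@R: person("photomics", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel (470 nm signal / 410 nm
    isosbestic control) fiber-photometry recordings: least-squares control-channel
    fitting, deltaF/F motion correction, z-scoring, peri-event bout analysis,
    threshold-based transient detection and event metrics (frequency, AUC,
    single-exponential decay tau). Companion differential-expression screen for
    proteomic, phosphoproteomic and transcriptomic abundance tables: fold-change
    plus t-test classification, screen summaries, gene-set intersection,
    hypergeometric enrichment factors and degree-based hub ranking. Seeded
    synthetic-data generators with known ground truth make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
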