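Package: ursensor
Title: Unique-Reporter Sensor Design, Quantification and Bayesian Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and analysis toolkit for unique-reporter (UR)
    transcription-factor sensor libraries. Generates 23-nt UR tag sequences
    under physicochemical and uniqueness constraints, assembles reporter
    constructs with their microarray capture oligos and qPCR assay primers,
    quantifies UR expression from qPCR Ct tables via standard-curve absolute
    quantification and from two-colour microarray spot tables, normalizes to
    a co-transfected Renilla luciferase control, and infers log2 fold
    induction per reporter with hierarchical Bayesian ANOVA models fitted by
    MCMC, reporting posterior means, 95% credible intervals, posterior tail
    p-values and significance calls. Includes a synthetic-data generator
    with known ground truth for end-to-end validation of both detection
    platforms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rjags,
    coda,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
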