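Package: affinityscan
Title: Total Binding Affinity Profiling of Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores DNA regulatory regions against collections of position
    weight matrices (PWMs) using total binding affinity (TBA), a cutoff-free
    thermodynamic quantity summing likelihood-ratio contributions from every
    subsequence on both strands, alongside cutoff-based occupancy and
    sum-of-scores alternatives.  Provides promoter construction around
    transcription start sites with optional chromatin-state masking and
    open-state extension, ROC/AUC evaluation of binding prediction across a
    score-cutoff sweep, and log-linear and lasso regression of gene
    expression on affinity profiles with cross-validation, shuffled-PWM and
    sequence-composition controls.  A synthetic-data module generates
    planted-motif benchmarks, chromatin segmentations and simulated
    expression so the whole workflow runs offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    glmnet,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
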