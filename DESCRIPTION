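Package: hrmdia
Title: Hyper Reaction Monitoring DIA Proteomics: Simulation, Targeted
    Extraction, Scoring and Differential Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end workflow for SWATH-type data-independent
    acquisition (DIA) proteomics in the hyper reaction monitoring (HRM)
    style: variable-width isolation-window scheme design, iRT-normalized
    consensus spectral libraries with scrambled decoys, targeted fragment
    chromatogram extraction with dynamic iRT calibration and interference
    detection, mProphet-style semi-supervised discriminant scoring with
    target-decoy peptide-level false discovery rates, MS2-level
    quantification with local retention-time normalization, and
    MSstats-style linear mixed-effects differential abundance testing with
    Benjamini-Hochberg adjustment and ROC/DeLong benchmarking. A bundled
    synthetic-data generator emulates a spike-in profiling standard sample
    set (constant background proteome, twelve spike-in proteins in three
    master mixes over eight samples, technical triplicates, block-randomized
    run order, DDA undersampling and truly-absent peptides) so the whole
    workflow can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
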