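Package: satellitome
Title: Satellitome Construction and Characterization from Assemblies and Reads
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds curated catalogues of satellite-DNA (satDNA) consensus
    monomers from genome assemblies and sequencing reads. Provides a
    self-contained local-alignment and hit-scanning engine, a k-mer
    periodicity tandem-array detector with multi-round masking, consensus
    building with a k-mer-coverage quality filter, redundancy removal by
    circular identity and Markov clustering of similarity graphs, screens
    for protein-coding, transposable-element, organellar and rDNA
    contamination, copy-number estimation from short and long reads with
    cross-validation and geometric-mean adjustment, per-read clustering
    metrics (MCNPR/MTSPR/MCOPR), correspondence analysis with Mahalanobis
    ranking of chromosome specificity, in-silico PCR, and a synthetic-data
    generator with ground-truth manifests for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    MASS,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
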