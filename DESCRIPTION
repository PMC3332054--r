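Package: rasosig
Title: Transcriptional Signature Analysis of RASopathy PBMC Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confound-aware analysis of peripheral-blood mononuclear cell (PBMC)
    expression microarrays for RASopathy cohorts (PTPN11, SOS1 and SHOC2
    mutation groups versus controls). Implements detection and confounder
    filtering, control-referenced log2-ratio transformation, triple-criterion
    differential-expression signature selection (fold change, t-test,
    signal-to-noise ratio), Monte Carlo permutation estimation of the
    false-positive fraction, full leave-one-out weighted-voting classification,
    hypergeometric gene-set over-representation, transcription-factor/target
    circuit detection, and unsupervised sample clustering. A synthetic-data
    generator emulating Illumina BeadChip-style PBMC matrices with planted
    signatures and confounder-correlated probes makes every stage testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    yaml,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
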