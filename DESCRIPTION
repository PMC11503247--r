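Package: m6adyn
Title: MeRIP-Seq m6A Methylome Analysis of the 2C-Like Cell State
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying N6-methyladenosine (m6A) RNA methylation
    from MeRIP-seq coverage and relating it to transcript dynamics during the
    2C-like to pluripotent state transition of mouse embryonic stem cells.
    Implements window-based m6A peak calling from IP versus input coverage,
    shuffle-null enrichment scores over gene features and transposable-element
    classes and families, per-gene methylation status and intensity, metagene
    profiles, gain/keep/lose/none m6A dynamics classification coupled to
    differential expression, marker-score single-cell state assignment with
    m6A-set fold-change contrasts, spike-in enrichment QC, delta-delta-Ct
    relative quantification and actinomycin-D decay half-life estimation.
    A synthetic-data generator emulates the statistical structure these
    analyses assume (stop-codon-proximal peaks with RRACH motifs, preferential
    methylation of zygotic-genome-activation transcripts and LTR/MERVL copies,
    three-state single-cell transitions, exponential decay courses) so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
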