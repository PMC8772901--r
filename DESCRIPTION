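Package: hybridexpr
Title: Inheritance-Mode and Heterosis Analysis for Reciprocal F1 Hybrid
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize gene-expression inheritance in reciprocal
    interspecific F1 hybrids from bulk RNA-seq count matrices. Provides RPKM
    normalization with an expressed-gene filter, pairwise differential
    expression via a negative-binomial exact test with Benjamini-Hochberg
    correction, classification of transgressive genes into concordant and
    discordant categories from parental and reciprocal-hybrid type means,
    phenotype-side mid-parent heterosis and heterobeltiosis statistics with
    exact Mann-Whitney U tests for small groups, and a seeded synthetic-data
    generator that plants known inheritance modes so the whole pipeline can
    be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    optparse
Config/testthat/edition: 3
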