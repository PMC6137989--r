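Package: h2azpipe
Title: Genic H2A.Z Deposition Analysis and Its Coupling to Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for analysing histone-variant H2A.Z
    deposition across genes and its relationship to transcription.
    Provides SICER-style broad-island calling from binned ChIP coverage,
    differential enrichment between conditions, TSS/gene-body partitioned
    peak-to-gene assignment, input-normalised metagene profiling with
    k-means deposition-pattern clustering, expression-quintile
    stratification, a negative-binomial differential-expression test,
    fuzzy k-means interaction clustering, hypergeometric term enrichment,
    and a bootstrap overlap-enrichment statistic linking H2A.Z changes to
    expression changes. A synthetic-data generator with a recorded truth
    table makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
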