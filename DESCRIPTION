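Package: dtcsig
Title: Consensus Drug-Tolerance Signatures from Bulk and Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus transcriptomic signatures of drug-tolerant
    persister cancer cells across multiple treatment models. Provides a
    negative-binomial Wald test for per-model differential expression on
    count data, an m-of-n cross-model consensus rule yielding up- and
    down-regulated signature gene lists (DTC_UP/DTC_DOWN), weighted
    Kolmogorov-Smirnov gene-set enrichment with permutation p-values and
    cross-model sharing tables, per-cell UMI-fraction gene-set scoring and
    cluster profiling for single-cell data, reference-gene phenotype
    association, random-partition pseudo-bulk aggregation, and FUCCI
    cell-cycle reporter track analysis (phase calling, population dynamics,
    and mitosis/endoreplication/death fate classification). Includes
    synthetic-data generators with planted ground truth for bulk models,
    clustered single-cell UMI matrices, and reporter tracks, so the whole
    pipeline can be exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    DESeq2,
    fgsea
Config/testthat/edition: 3
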