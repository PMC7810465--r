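Package: sepstager
Title: Staging Bulk Transcriptomes Along a Single-Cell Endotoxemia Time Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives time-point-defining transcriptomic signatures from a
    single-cell endotoxemia (LPS) time course and uses them to stage bulk
    query samples, such as human sepsis-associated acute kidney injury
    biopsies, along the murine timeline. Provides cell-level quality
    filtering, seeded subsampling and pseudobulk aggregation; a
    negative-binomial differential-expression engine with trimmed-mean
    (TMM) normalization, moment-based dispersion estimation, Wald tests
    and Benjamini-Hochberg correction; orthologue translation of
    signatures; Spearman-correlation stage assignment with severity
    (SOFA) association testing; pseudobulk-versus-bulk Jaccard gene-set
    concordance with complete-linkage ordering; and a synthetic-data
    generator so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
Config/testthat/edition: 3
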