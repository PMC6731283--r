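Package: degas
Title: Decomposition of Genetic Associations from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Assembles a phenome-by-genome Z-score matrix from per-phenotype
    GWAS summary statistics under variant quality-control and value-based
    filters, factorizes it with truncated singular value decomposition, and
    interprets the latent components with contribution scores, squared cosine
    scores, biplot projections, regulatory-domain binomial region enrichment,
    and term-set Jaccard specificity profiles. Includes a synthetic-data
    generator that plants low-rank latent structure so the whole pipeline can
    be exercised and validated without access-controlled biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
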