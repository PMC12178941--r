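Package: pmvnet
Title: Triangle Motif Census and Principal Motif Values for Regional
    Radiomics Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds regional radiomics similarity networks (R2SN) from
    per-subject region-by-feature tables, classifies every triangle of the
    complete network into one of 20 edge-labelled motif types using
    cohort-median strength and length thresholds, and summarises the
    20-type regional motif census into a per-region Principal Motif Value
    (PMV) by principal component analysis with a deterministic sign
    convention.  Provides the accompanying nonparametric group statistics
    (per-region Kruskal-Wallis maps, Mann-Whitney Z maps with Bonferroni
    control, Stouffer meta-analysis across sites), clinical correlation
    maps, partition summaries, and spatial association tools
    (one-component partial least squares with permutation nulls,
    bootstrap gene Z-scores with top-k export, and map correlation
    panels).  A seeded synthetic-cohort generator produces atlases,
    group-structured feature tables, clinical scores and spatial maps
    with planted regional effects, so the full pipeline is testable
    end-to-end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics,
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
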