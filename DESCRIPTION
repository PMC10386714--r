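Package: trfscope
Title: tRNA-Derived Fragment Classification, m7G Cleavage Mapping and
    Cross-Cohort Expression Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse tRNA-derived small RNA fragments (tRFs) and
    N7-methylguanosine (m7G) tRNA methylation. Classifies small-RNA reads
    aligned on mature tRNA references into 3' tRFs, internal tRFs, 5' tRFs,
    5' halves and 5' terminal-oligoguanine (5'TOG) fragments; tests
    differential fragment abundance between conditions with a
    negative-binomial Wald test using median-of-ratios normalisation; maps
    aniline-cleavage (AlkAniline-seq) stop sites to call m7G positions in
    the tRNA variable loop using knockout profiles as controls; screens
    RNA-modifying-protein expression across tumour cohorts by Z-score,
    per-cohort ANOVA and cross-cohort coherence; and quantifies PAR-CLIP
    and polysome-profiling outputs. Includes synthetic-data generators
    that emulate each input so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
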