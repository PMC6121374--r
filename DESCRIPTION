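Package: crpffl
Title: Feed-Forward Loop Census and cAMP Dose-Response Profiling of the
    CRP Regulon
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing feed-forward loops (FFLs) anchored on a
    master transcription factor such as the Escherichia coli cAMP receptor
    protein (CRP).  Reads signed regulator-target interaction tables,
    enumerates all FFL triangles through a master regulator, classifies
    them into the eight coherent/incoherent types, and partitions them
    into single-Y and multi-Y loops.  Turns log2 expression matrices over
    a cAMP dose series into per-gene dose-response fold-change profiles,
    applies a fold-change responsiveness filter, clusters profiles by
    Pearson correlation with average linkage, labels canonical profile
    shapes, merges single-Y and multi-Y groups into functional groups,
    and scores gene-set GO over-representation with the hypergeometric
    test.  Seeded synthetic generators for networks with planted motif
    composition, dose-response profiles with canonical shapes, and
    annotation sets with planted enriched terms make every pipeline stage
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
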