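Package: hiergrn
Title: Hierarchical Gene Regulatory Network Inference from Stress
    Time-Course Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers three-layer hierarchical gene regulatory networks
    (TF -> TF -> structural gene) from time-course expression matrices
    using triple-gene partial-correlation attribution: co-expressed gene
    pairs are detected by Pearson correlation and attributed to a
    transcription-factor regulator when conditioning on that factor
    collapses the pair correlation.  Includes a differential-expression
    filter against the unstressed control, hypergeometric (central and
    Wallenius non-central) GO term enrichment of the bottom layer,
    classification of experimentally tested TF-target interactions as
    direct (promoter binding) or indirect (expression response), a
    comparative-CT relative-expression helper, a synthetic-data simulator
    with planted ground-truth hierarchies for benchmarking recovery, and
    readers/writers for TSV, SIF and GraphML network formats plus an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
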