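Package: starmna
Title: Scaffold-Based Multiple Alignment of Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combines any set of pairwise protein-protein interaction network
    alignments computed against a common scaffold network into a single
    multiple network alignment, using a star-alignment heuristic. Computes
    per-scaffold-node co-alignment clusters and per-scaffold-edge conserved
    (induced) interaction clusters, selects a scaffold network by summed
    pairwise similarity, converts native multiple alignments into
    scaffold-rooted form for comparison, and scores alignments with a suite
    of functional-similarity, homology and edge-conservation measures,
    including conservation breadth across species and precision of implied
    correspondences. A synthetic generator produces multi-species network
    families with planted orthology for validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
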