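Package: divrank
Title: Diversity-Aware Re-Ranking of Sequence Similarity Search Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processes protein similarity search results (BLAST or
    PSI-BLAST reports) to produce a diversity-ranked subset of hits.
    Aligned fragments are projected onto a query-anchored star alignment
    and greedily re-ranked with two selection rules: average-linkage
    Hamming distance over aligned-position bit masks, and normalized
    Shannon entropy of the growing selection at the residue and bit
    levels. Result sets are scored with a Rao quadratic-entropy sequence
    diversity measure over a BLOSUM62-derived symbol dissimilarity
    matrix, with query-coverage statistics, and with a Gene Ontology
    functional dissimilarity based on Wang-style semantic similarity on
    the molecular-function ontology. Includes readers for BLAST XML and
    tabular reports, an OBO/GAF loader, a deterministic synthetic
    fixture generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
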