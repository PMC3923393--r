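Package: cdkcyclin
Title: Subfamily Classification and Phylogenetic Profiling of CDK and
    Cyclin Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for assigning cyclin-dependent kinase (CDK) and
    cyclin proteins from eukaryotic proteomes to named subfamilies.
    Candidate sequences are curated by longest-isoform selection, Pfam
    domain-presence filtering and reciprocal-best-hit exclusion of
    non-family look-alikes; queries are then classified by the clade they
    form with human reference proteins in maximum-likelihood gene trees
    (requiring more than 50 percent bootstrap support), with a fallback
    criterion based on a five-orders-of-magnitude E-value margin between
    the best and next-best subfamily, and remaining proteins designated
    unclassified.  Results are summarised as per-organism counts and
    organism-by-subfamily presence/absence profiles.  A gene
    duplication-loss simulator over a species tree, with emulated
    bootstrap supports and similarity E-values, provides fully labelled
    synthetic benchmarks so every stage can be tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
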