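Package: ksage
Title: Whole-Genome Duplication Detection and Dating from Ks Age Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and date whole-genome duplications (WGDs) from
    genomic data: paranome inference with gene-length-bias correction of
    similarity bit-scores and Markov clustering, synonymous-substitution (Ks)
    age distributions with NG86 estimates and node-weighted or node-averaged
    event deduplication, collinear (syntenic) segment detection with dupstack,
    syndepth and dot-plot summaries, trio-based substitution-rate correction
    with bootstrap KDE modes, exponential-lognormal and log-scale Gaussian
    mixture modelling of Ks distributions, and anchor-pair filtering with
    orthogroup assembly for absolute WGD dating. A synthetic-data module
    generates gene families, codon pairs evolved to a target Ks, genomes with
    implanted duplicated segments, and Ks mixture samples, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
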