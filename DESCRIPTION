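Package: provirome
Title: Mining and Characterising Viral Sequences from Microbial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the post-detection analysis of viral sequences mined
    from bacterial and archaeal genome projects: curation of viral predictions
    (hallmark-gene, length and circularity filters), classification of curated
    sequences by replication mode, gene-content clustering of viral genomes
    into genus-level virus clusters (reciprocal-best-hit protein clustering,
    hypergeometric shared-gene significance, Markov clustering), majority-rule
    and lowest-common-ancestor taxonomic affiliation, bipartite virus-host
    modularity (Barber's Q maximised by label-propagation-seeded BRIM with a
    permutation null), genome-composition adaptation metrics (k-mer frequency
    distances, codon adaptation index, Kolmogorov-Smirnov comparisons),
    composition-based host prediction with leave-species-out and
    leave-genus-out evaluation, and co-infection statistics with a terminase
    large-subunit safeguard. A seeded synthetic-world generator with known
    ground truth exercises the whole pipeline end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
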