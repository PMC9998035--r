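Package: armroot
Title: Duplication-Rooted Phylogenetics and Loss-History Analysis for
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of multi-subunit protein
    complexes across a species phylogeny: presence/absence profiling with
    co-occurrence and mutual-exclusivity statistics, Dollo (single-gain)
    parsimony reconstruction of independent losses, paralogy inference from
    profile-versus-profile E-value tables, rigid-body (Kabsch) superposition
    of structural paralogs, construction of duplication-rooted "arm"
    supermatrices from paralogous subunit pairs, desk-scale maximum-likelihood
    tree inference with RELL/KH/AU topology testing, and genomic
    co-localization summaries. A synthetic-data module simulates birth-death
    species trees, coupled Dollo loss histories, duplication-structured
    subunit sequences and scaffold layouts so that every stage of the
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
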