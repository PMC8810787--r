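Package: protochrom
Title: Ancestral Gene Orders, Protochromosomes and Genome-History Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs ancestral gene orders at internal nodes of a
    species tree from syntenic homolog pairs and extant gene orders.
    Gene families are built as connected components of the homology graph,
    window-based generalized adjacencies are extracted from each genome,
    candidate ancestral adjacencies supported by two or three of the
    subtrees incident to an ancestor node are assembled into ancestral
    contigs by exact maximum-weight matching of protogene ends, and
    contigs are clustered into protochromosomes by complete-linkage
    clustering of their co-occurrence on modern chromosomes. Downstream
    analyses include chromosome painting with an inter-chromosomal
    exchange ("choppiness") count, syntenic-depth profiling of ploidy
    ratios, and a topology-consistency scan over the peaks of Ks and
    similarity distributions of syntenic homologs. A genome-evolution
    simulator (whole-genome duplications, two-step hexaploidy,
    fractionation, inversions, reciprocal translocations, fusions and
    fissions, clock-like Ks) provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    mclust,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
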