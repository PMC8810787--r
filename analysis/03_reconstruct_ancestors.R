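#!/usr/bin/env Rscript
# Reconstruct ancestral gene orders at the three internal nodes above the
# core radiation: candidate adjacencies supported by two or three of each
# node's incident subtrees are assembled into contigs by exact
# maximum-weight matching of protogene ends, contigs are clustered into
# seven protochromosomes by complete-linkage on co-occurrence correlations,
# and ordered against a reference genome. Because the data are simulated,
# every reconstruction is scored against the true ancestral adjacencies.

library(protochrom)

sim <- readRDS("results/data/simulation.rds")
orders <- sim$orders
pairs <- sim$pairs
tree <- sim$tree

families <- build_families(pairs, genomes = orders, max_copies_per_genome = 5)
adj <- extract_generalized_adjacencies(orders, families, w = 7)

ancestors <- c("n2", "n3", "n4")   # eudicot-like, Bux+Tet+core, Bux+Tet nodes
scores <- list()
for (anc in ancestors) {
  contigs <- reconstruct_ancestor(orders, families, tree, anc, w = 7,
                                  adjacencies = adj)
  ancestor <- assemble_protochromosomes(contigs, orders, families, k = 7,
                                        reference_genome = "ran")
  write_ancestor(ancestor, sprintf("results/ancestor_%s.tsv", anc))

  inferred <- as_true_pairs(contig_adjacencies(contigs), sim)
  truth <- true_adjacencies(sim, anc)
  topo <- attr(contigs, "topology")
  scores[[anc]] <- data.frame(
    ancestor = anc,
    protogenes = nrow(ancestor),
    contigs = nrow(topo),
    cycles_broken = sum(topo$topology == "circularized"),
    matched_weight = attr(contigs, "total_weight"),
    recall = round(length(intersect(inferred, truth)) / length(truth), 4),
    precision = round(length(intersect(inferred, truth)) / length(inferred), 4))
  message(sprintf("%s: %d protogenes in %d contigs, recall %.3f precision %.3f",
                  anc, nrow(ancestor), nrow(topo),
                  scores[[anc]]$recall, scores[[anc]]$precision))
}
scores <- do.call(rbind, scores)
write.table(scores, "results/reconstruction_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
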