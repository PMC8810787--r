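#!/usr/bin/env Rscript
# Build disjoint gene families from the homolog pairs (connected components
# of the homology graph) and extract window-based generalized adjacencies
# (all gene pairs within seven consecutive genes, joined by their facing
# ends) from every genome.

library(protochrom)

orders <- read_gene_orders("results/data/gene_orders.tsv")
pairs <- read_homolog_pairs("results/data/homolog_pairs.tsv", genomes = orders)

families <- build_families(pairs, genomes = orders, max_copies_per_genome = 5)
print(families)
write.table(families$membership, "results/families.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

adj <- extract_generalized_adjacencies(orders, families, w = 7)
write.table(adj, "results/adjacencies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(adj), " generalized adjacencies at window 7 across ",
        length(unique(adj$genome)), " genomes")
print(table(adj$genome, adj$distance)[, 1:3])
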