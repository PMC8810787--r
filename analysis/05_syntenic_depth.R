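#!/usr/bin/env Rscript
# Syntenic-depth profiling: chain true orthologs into synteny blocks and
# read reciprocal modal depths as ploidy ratios. The expected signature of
# the simulated history is 2:3 (one-WGD lineage vs two-step hexaploid),
# 4:3 (two-WGD lineage vs hexaploid) and 4:2.

library(protochrom)

sim <- readRDS("results/data/simulation.rds")
gset <- sort(unique(sim$orders$genome))
rows <- list()
for (i in seq_along(gset)) for (j in seq_along(gset)) {
  if (i >= j) next
  blocks <- make_synteny_blocks(sim$orders, sim$pairs, gset[i], gset[j])
  if (!nrow(blocks)) next
  dr <- depth_ratio(blocks, gset[i], gset[j], bin = 50)
  rows[[length(rows) + 1L]] <- data.frame(
    genome_a = gset[i], genome_b = gset[j], blocks = nrow(blocks) / 2L,
    ratio = dr$ratio)
}
depth <- do.call(rbind, rows)
write.table(depth, "results/syntenic_depth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(depth, row.names = FALSE)
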