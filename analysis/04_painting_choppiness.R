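#!/usr/bin/env Rscript
# Paint the modern genomes by protochromosome of origin for each
# reconstructed ancestor and count inter-chromosomal exchanges
# ("choppiness"). Genomes should look less choppy against nearer ancestors:
# rearrangements that predate a node are absorbed into its reconstruction.

library(protochrom)

sim <- readRDS("results/data/simulation.rds")
families <- build_families(sim$pairs, genomes = sim$orders,
                           max_copies_per_genome = 5)

rows <- list()
for (anc in c("n2", "n3", "n4")) {
  ancestor <- read_ancestor(sprintf("results/ancestor_%s.tsv", anc))
  for (g in c("coreA", "coreB", "bux", "tet")) {
    p <- paint(sim$orders, ancestor, families, genome_id = g,
               min_segment = 5, smooth_window = 1)
    write_painting(p, sprintf("results/painting_%s_%s.bed", g, anc))
    rows[[length(rows) + 1L]] <- data.frame(
      genome = g, ancestor = anc, segments = nrow(p),
      exchanges = count_exchanges(p)$total)
  }
}
chop <- do.call(rbind, rows)
write.table(chop, "results/choppiness.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("inter-chromosomal exchanges by genome x ancestor:")
print(stats::xtabs(exchanges ~ genome + ancestor, chop))
core_near <- chop$exchanges[chop$genome == "coreA" & chop$ancestor == "n3"]
core_far <- chop$exchanges[chop$genome == "coreA" & chop$ancestor == "n2"]
message(sprintf("coreA: %d exchanges vs the nearer ancestor, %d vs the farther",
                core_near, core_far))
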