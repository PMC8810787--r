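#!/usr/bin/env Rscript
# 'Trees in the Peaks': estimate the primary Ks peak of every genome pair's
# ortholog distribution and keep only the rooted topologies in which every
# ancestral node precedes or overlaps its descendants. With six leaves
# there are 945 rooted binary topologies; the clock-like simulation should
# leave (a superset including) the generating one.

library(protochrom)

sim <- readRDS("results/data/simulation.rds")
gmap <- stats::setNames(sim$orders$genome, sim$orders$gene_id)
ga <- gmap[sim$pairs$gene_a]
gb <- gmap[sim$pairs$gene_b]
ok <- ga != gb & sim$pairs$pair_class == "ortholog"
key <- paste(pmin(ga, gb), pmax(ga, gb), sep = "|")

pair_peaks <- lapply(split(sim$pairs$ks[ok], key[ok]), estimate_peaks,
                     axis = "ks")
modes <- vapply(pair_peaks, function(p) primary_peak(p)$mode, 0)
message("primary ortholog Ks modes per genome pair:")
print(round(sort(modes), 3))

verdicts <- trees_in_peaks(pair_peaks, axis = "ks")
write.table(verdicts, "results/treescan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cons <- verdicts$topology[verdicts$consistent]
message(sum(verdicts$consistent), " of ", nrow(verdicts),
        " rooted topologies are peak-consistent")
writeLines(cons, "results/consistent_topologies.nwk")
gen <- topology_newick(list("ran", list("pro", list(list("bux", "tet"),
                                                    list("coreA", "coreB")))))
message("generating topology among them: ", gen %in% cons)
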