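two_contigs <- function() {
  df <- data.frame(contig_id = c("C0001", "C0001", "C0002"),
                   position = c(0L, 1L, 0L),
                   family_id = c("f1", "f2", "f3"),
                   join_weight = c(3L, NA, NA))
  structure(df, class = c("ancestral_contigs", "data.frame"))
}

test_that("occurrence matrix counts families with members on each chromosome", {
  g <- as_gene_orders(data.frame(
    genome = "V", chromosome = c("v1", "v1", "v2"),
    gene_id = c("a1", "a2", "a3"), strand = "+", rank = c(0L, 1L, 0L)))
  fam <- structure(list(
    membership = data.frame(gene_id = c("a1", "a2", "a3"),
                            family_id = c("f1", "f2", "f2")),
    families = data.frame(family_id = c("f1", "f2"), n_genes = c(1L, 2L),
                          oversize = FALSE),
    max_copies_per_genome = 5L), class = "gene_families")
  occ <- map_contigs(two_contigs(), g, fam)
  # contig C0001 = {f1, f2}: both on v1, f2 also on v2
  expect_equal(occ$counts["C0001", "V:v1"], 2L)
  expect_equal(occ$counts["C0001", "V:v2"], 1L)
  # contig C0002 = {f3}: nowhere -> zero row, retained
  expect_equal(sum(occ$counts["C0002", ]), 0L)
  expect_equal(unname(rowSums(occ$proportions)["C0001"]), 1)
})

test_that("identical occurrence vectors cluster together, disjoint ones apart", {
  counts <- rbind(C1 = c(5L, 0L, 0L), C2 = c(4L, 0L, 0L),
                  C3 = c(0L, 6L, 0L), C4 = c(0L, 0L, 3L))
  colnames(counts) <- c("G:c1", "G:c2", "G:c3")
  occ <- structure(list(counts = counts,
                        proportions = counts / pmax(rowSums(counts), 1)),
                   class = "occurrence_matrix")
  asg <- cluster_contigs(occ, k = 3)
  cl <- stats::setNames(asg$protochromosome_id, asg$contig_id)
  expect_equal(cl[["C1"]], cl[["C2"]])
  expect_length(unique(cl[c("C1", "C3", "C4")]), 3L)
  expect_error(cluster_contigs(occ, k = 0), "k must be")
  expect_error(cluster_contigs(occ, k = 9), "k must be")
})

test_that("contigs are ordered by median reference rank, ties by id", {
  genes <- sprintf("r%02d", 1:60)
  g <- toy_orders(genes, genome = "R")
  fam <- identity_families(genes)
  contigs <- structure(data.frame(
    contig_id = rep(c("C0001", "C0002"), each = 3),
    position = rep(0:2, 2),
    family_id = c(genes[40:42], genes[5:7]),   # C0002 sits earlier on R
    join_weight = NA_integer_),
    class = c("ancestral_contigs", "data.frame"))
  asg <- structure(data.frame(contig_id = c("C0001", "C0002"),
                              protochromosome_id = c(1L, 1L)),
                   class = c("proto_assignment", "data.frame"))
  anc <- order_within(asg, contigs, g, fam, reference_genome = "R")
  expect_equal(anc$contig_id, rep(c("C0002", "C0001"), each = 3))
  expect_equal(anc$position, 0:5)
})

test_that("protogene count is conserved through assembly", {
  set.seed(91)
  ev <- list(A = list(wgd = 1L, fractionation = 0.2, inversions = 2L))
  cfg <- new_evolution_config("((A:0.3,B:0.3)anc:0.3,C:0.6)root;", seed = 9,
                              events = ev, n_chromosomes = 4,
                              genes_per_chromosome = 30)
  sim <- simulate_evolution(cfg)
  fam <- build_families(sim$pairs, genomes = sim$orders)
  contigs <- reconstruct_ancestor(sim$orders, fam, sim$tree, "anc")
  anc <- assemble_protochromosomes(contigs, sim$orders, fam, k = 4,
                                   reference_genome = "B")
  asg <- attr(anc, "assignment")
  unplaced <- sum(is.na(asg$protochromosome_id[match(contigs$contig_id,
                                                     asg$contig_id)]))
  expect_equal(nrow(anc) + unplaced, nrow(contigs))
  expect_equal(length(unique(anc$protochromosome_id)), 4L)
})

test_that("translocation-free simulation recovers the true contig clustering", {
  ev <- list(A = list(wgd = 1L, fractionation = 0.15, inversions = 3L),
             B = list(inversions = 3L), C = list(inversions = 3L))
  cfg <- new_evolution_config("((A:0.3,B:0.3)anc:0.3,C:0.6)root;", seed = 13,
                              events = ev)
  sim <- simulate_evolution(cfg)
  fam <- build_families(sim$pairs, genomes = sim$orders)
  contigs <- reconstruct_ancestor(sim$orders, fam, sim$tree, "anc")
  occ <- map_contigs(contigs, sim$orders, fam)
  asg <- cluster_contigs(occ, k = 7)
  got <- family_cluster_labels(asg, contigs)
  want <- true_origin_labels(names(got), sim)
  keep <- !is.na(got)
  expect_equal(mclust::adjustedRandIndex(got[keep], want[keep]), 1.0)
})
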