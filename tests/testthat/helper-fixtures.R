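# small in-code fixtures shared across test files

# a single-genome, single-chromosome gene order with given strands
toy_orders <- function(genes, strands = NULL, genome = "G", chrom = "c1") {
  n <- length(genes)
  if (is.null(strands)) strands <- rep("+", n)
  as_gene_orders(data.frame(
    genome = genome, chromosome = chrom, gene_id = genes,
    strand = strands, rank = seq_len(n) - 1L, stringsAsFactors = FALSE))
}

# gene_families where every gene is its own family (identity map)
identity_families <- function(genes) {
  structure(list(
    membership = data.frame(gene_id = genes, family_id = genes,
                            stringsAsFactors = FALSE),
    families = data.frame(family_id = genes, n_genes = 1L, oversize = FALSE,
                          stringsAsFactors = FALSE),
    max_copies_per_genome = 5L
  ), class = "gene_families")
}

# candidate_adjacencies from compact triples list(fa, fb, weight), with
# canonical facing ends (fa side 1 -- fb side 0) unless sides are given
toy_candidates <- function(..., sides = NULL) {
  rows <- list(...)
  df <- data.frame(
    family_a = vapply(rows, function(r) as.character(r[[1]]), ""),
    family_b = vapply(rows, function(r) as.character(r[[2]]), ""),
    weight = vapply(rows, function(r) as.integer(r[[3]]), 0L),
    stringsAsFactors = FALSE)
  if (is.null(sides)) {
    df$side_a <- 1L
    df$side_b <- 0L
  } else {
    df$side_a <- vapply(sides, `[`, 0L, 1L)
    df$side_b <- vapply(sides, `[`, 0L, 2L)
  }
  df$distance <- 1L
  structure(df, class = c("candidate_adjacencies", "data.frame"))
}

# precision/recall of reconstructed joins against true neighbor adjacencies
adjacency_pr <- function(contigs, sim, node) {
  inferred <- as_true_pairs(contig_adjacencies(contigs), sim)
  truth <- true_adjacencies(sim, node)
  c(recall = length(intersect(inferred, truth)) / length(truth),
    precision = length(intersect(inferred, truth)) / length(inferred))
}

# family-level cluster labels induced by a contig clustering (used for ARI:
# contig-level labels degenerate to all-singletons when contigs are
# chromosome-scale)
family_cluster_labels <- function(assignment, contigs) {
  cl <- stats::setNames(assignment$protochromosome_id, assignment$contig_id)
  stats::setNames(cl[contigs$contig_id], contigs$family_id)
}

true_origin_labels <- function(fams, sim) {
  sim$truth$fam_origin[sim$truth$family_map[fams]]
}

# end-to-end reconstruction for one ancestor of a simulation
sim_reconstruct <- function(sim, ancestor, w = 7L) {
  fam <- build_families(sim$pairs, genomes = sim$orders)
  reconstruct_ancestor(sim$orders, fam, sim$tree, ancestor, w = w)
}

# preset with the stress-test overrides used across tests
preset_stress <- function(seed, fractionation = 0.2, inversions = 5L) {
  cfg <- preset_eudicot(seed = seed)
  for (nm in names(cfg$events)) {
    cfg$events[[nm]]$fractionation <- fractionation
    cfg$events[[nm]]$inversions <- inversions
  }
  cfg
}

# random 4-port candidate edge set on <= max_fam families (matching oracle
# fixtures)
random_port_edges <- function(max_fam = 8L) {
  nf <- sample(3:max_fam, 1L)
  fams <- sprintf("f%02d", seq_len(nf))
  prs <- t(utils::combn(nf, 2L))
  sel <- prs[stats::runif(nrow(prs)) < 0.6, , drop = FALSE]
  if (!nrow(sel)) sel <- prs[1L, , drop = FALSE]
  w <- sample(2:3, nrow(sel), TRUE)
  ends <- expand.grid(sa = 0:1, sb = 0:1)
  do.call(rbind, lapply(1:4, function(k) data.frame(
    u = paste0(fams[sel[, 1]], ".", ends$sa[k]),
    v = paste0(fams[sel[, 2]], ".", ends$sb[k]),
    w = w, stringsAsFactors = FALSE)))
}
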