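balanced4 <- ape::read.tree(text = "((A:1,B:1)n1:1,(C:1,D:1)n2:1)root;")
caterpillar4 <- ape::read.tree(text = "(((A:1,B:1)x:1,C:2)y:1,D:3)root;")

test_that("an ancestor node partitions leaves into its three incident subtrees", {
  p1 <- partition_subtrees(balanced4, "n1")
  expect_equal(p1$subtrees, list("A", "B", c("C", "D")))
  p2 <- partition_subtrees(balanced4, "n2")
  expect_equal(p2$subtrees, list("C", "D", c("A", "B")))
  py <- partition_subtrees(caterpillar4, "y")
  expect_equal(py$subtrees, list(c("A", "B"), "C", "D"))
})

test_that("the root is refused unless two-subtree mode is requested", {
  expect_error(partition_subtrees(balanced4, "root"), "root_mode")
  pr <- partition_subtrees(balanced4, "root", root_mode = TRUE)
  expect_length(pr$subtrees, 2L)
})

test_that("candidate weights count supporting subtrees, not occurrences", {
  part <- partition_subtrees(balanced4, "n1")
  adj_row <- function(genome, fa, fb, d = 1L) data.frame(
    genome = genome, chromosome = "c1", gene_a = "x", gene_b = "y",
    family_a = fa, family_b = fb, side_a = 1L, side_b = 0L,
    distance = d, tandem = FALSE, stringsAsFactors = FALSE)
  # {f,g} in subtrees 1 and 3 -> weight 2
  adj <- rbind(adj_row("A", "f", "g"), adj_row("C", "f", "g"),
               # {f,h} in all three subtrees -> weight 3
               adj_row("A", "f", "h"), adj_row("B", "f", "h"),
               adj_row("D", "f", "h"),
               # {g,h} twice, but both in subtree 3 -> not a candidate
               adj_row("C", "g", "h"), adj_row("D", "g", "h"))
  cand <- collect_candidates(adj, part)
  expect_equal(cand$weight[cand$family_a == "f" & cand$family_b == "g"], 2L)
  expect_equal(cand$weight[cand$family_a == "f" & cand$family_b == "h"], 3L)
  expect_false(any(cand$family_a == "g" & cand$family_b == "h"))
})

test_that("forced chain assembles into a single linear contig", {
  contigs <- mwm_assemble(toy_candidates(list("a", "b", 3), list("b", "c", 3)))
  expect_equal(length(unique(contigs$contig_id)), 1L)
  expect_equal(contigs$family_id, c("a", "b", "c"))
  expect_equal(attr(contigs, "total_weight"), 6)
  expect_equal(attr(contigs, "topology")$topology, "linear")
})

test_that("families untouched by matched adjacencies become singleton contigs", {
  contigs <- mwm_assemble(toy_candidates(list("a", "b", 3)),
                          eligible = c("a", "b", "zz"))
  topo <- attr(contigs, "topology")
  expect_equal(sort(topo$length), c(1L, 2L))
  expect_true("zz" %in% contigs$family_id)
})

test_that("cycles are broken at the minimum-weight join", {
  # 3-cycle a-b (3), b-c (3), c-a (2): break {a,c}
  cand <- toy_candidates(list("a", "b", 3), list("b", "c", 3), list("a", "c", 2),
                         sides = list(c(1L, 0L), c(1L, 0L), c(0L, 1L)))
  raw <- mwm_assemble(cand)
  expect_equal(attr(raw, "topology")$topology, "circular")
  lin <- linearize(raw)
  topo <- attr(lin, "topology")
  expect_equal(topo$topology, "circularized")
  expect_equal(lin$family_id, c("a", "b", "c"))
  expect_setequal(contig_adjacencies(lin), c("a|b", "b|c"))
  expect_equal(attr(lin, "total_weight"), 6)
})

test_that("cycle ties break at the lexicographically smallest family pair", {
  cand <- toy_candidates(list("a", "b", 3), list("b", "c", 3), list("a", "c", 3),
                         sides = list(c(1L, 0L), c(1L, 0L), c(0L, 1L)))
  lin <- linearize(mwm_assemble(cand))
  # {a,b} removed: remaining joins are a|c and b|c
  expect_setequal(contig_adjacencies(lin), c("a|c", "b|c"))
})

test_that("linearize leaves linear contigs unchanged", {
  contigs <- mwm_assemble(toy_candidates(list("a", "b", 3), list("b", "c", 2)))
  expect_identical(linearize(contigs), contigs)
})

test_that("every contig set is cycle-free after linearization", {
  set.seed(81)
  for (i in 1:20) {
    nf <- sample(4:9, 1)
    fams <- sprintf("f%02d", seq_len(nf))
    prs <- t(utils::combn(nf, 2))
    sel <- prs[stats::runif(nrow(prs)) < 0.5, , drop = FALSE]
    if (!nrow(sel)) next
    cand <- do.call(toy_candidates, c(
      lapply(seq_len(nrow(sel)), function(r)
        list(fams[sel[r, 1]], fams[sel[r, 2]], sample(2:3, 1))),
      list(sides = lapply(seq_len(nrow(sel)), function(r)
        c(sample(0:1, 1), sample(0:1, 1))))))
    lin <- linearize(mwm_assemble(cand))
    expect_false(any(attr(lin, "topology")$topology == "circular"))
    # last join of every contig is NA once linear
    last <- tapply(seq_len(nrow(lin)), lin$contig_id, max)
    expect_true(all(is.na(lin$join_weight[last])))
  }
})

test_that("a clean 3-leaf simulation is reconstructed exactly", {
  cfg <- new_evolution_config("((A:0.3,B:0.3)anc:0.3,C:0.6)root;", seed = 7,
                              n_chromosomes = 3, genes_per_chromosome = 40)
  sim <- simulate_evolution(cfg)
  contigs <- sim_reconstruct(sim, "anc")
  pr <- adjacency_pr(contigs, sim, "anc")
  expect_equal(unname(pr["recall"]), 1)
  expect_equal(unname(pr["precision"]), 1)
  # contigs concatenate to the true ancestral order per chromosome, up to
  # whole-contig reversal
  topo <- attr(contigs, "topology")
  expect_equal(nrow(topo), 3L)
  fm <- sim$truth$family_map
  true_chroms <- lapply(split(true_ancestor(sim, "anc"),
                              true_ancestor(sim, "anc")$protochromosome_id),
                        function(d) d$family_id)
  for (cid in topo$contig_id) {
    fams <- fm[contigs$family_id[contigs$contig_id == cid]]
    hit <- vapply(true_chroms, function(tc)
      identical(unname(fams), tc) || identical(unname(rev(fams)), tc), TRUE)
    expect_equal(sum(hit), 1L)
  }
})

test_that("increasing fractionation does not increase true-adjacency recall", {
  recalls <- vapply(c(0, 0.15, 0.35), function(p) {
    rs <- vapply(1:4, function(s) {
      ev <- list(A = list(wgd = 1L, fractionation = p),
                 B = list(), C = list())
      cfg <- new_evolution_config("((A:0.3,B:0.3)anc:0.3,C:0.6)root;",
                                  seed = 100 + s, events = ev,
                                  n_chromosomes = 2,
                                  genes_per_chromosome = 50)
      sim <- simulate_evolution(cfg)
      adjacency_pr(sim_reconstruct(sim, "anc"), sim, "anc")["recall"]
    }, 0)
    mean(rs)
  }, 0)
  expect_true(recalls[1] >= recalls[2] - 0.02)
  expect_true(recalls[2] >= recalls[3] - 0.02)
})
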