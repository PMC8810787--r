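label_painting <- function(labels, min_segment = 1L, smooth_window = 1L) {
  genes <- sprintf("p%02d", seq_along(labels))
  g <- toy_orders(genes)
  fam <- identity_families(genes)
  anc <- data.frame(protochromosome_id = labels[!is.na(labels)],
                    position = seq_len(sum(!is.na(labels))) - 1L,
                    family_id = genes[!is.na(labels)],
                    contig_id = "C0001", adjacency_support = NA_integer_)
  paint(g, anc, fam, min_segment = min_segment, smooth_window = smooth_window)
}

test_that("runs of labels become half-open segments tiling the chromosome", {
  p <- label_painting(c(1, 1, 1, 2, 2, 2))
  expect_equal(p$start, c(0L, 3L))
  expect_equal(p$end, c(3L, 6L))
  expect_equal(p$label, c("1", "2"))
})

test_that("short runs merge into the flanking majority label", {
  p <- label_painting(c(1, 1, 2, 1, 1), min_segment = 2)
  expect_equal(nrow(p), 1L)
  expect_equal(p$label, "1")
  expect_equal(c(p$start, p$end), c(0L, 5L))
  # min_segment = 1 keeps the interloper
  p1 <- label_painting(c(1, 1, 2, 1, 1), min_segment = 1)
  expect_equal(nrow(p1), 3L)
})

test_that("paintings tile every chromosome without gaps or overlaps", {
  set.seed(101)
  for (i in 1:10) {
    labels <- sample(c(1:3, NA), 30, TRUE)
    p <- label_painting(labels, min_segment = sample(1:4, 1))
    expect_equal(p$start, c(0L, p$end[-nrow(p)]))
    expect_equal(p$end[nrow(p)], 30L)
    expect_true(all(p$end > p$start))
  }
})

test_that("exchange counting: boundaries between differently painted segments", {
  expect_equal(count_exchanges(label_painting(c(1, 1, 1)))$total, 0L)
  expect_equal(count_exchanges(label_painting(c(1, 1, 2, 2, 1, 1)))$total, 2L)
  # unpainted runs are transparent: 1 NA 2 counts once, 1 NA 1 not at all
  expect_equal(count_exchanges(label_painting(c(1, 1, NA, 2, 2)))$total, 1L)
  expect_equal(count_exchanges(label_painting(c(1, 1, NA, 1, 1)))$total, 0L)
})

test_that("exchange count is invariant to whole-chromosome reversal", {
  set.seed(111)
  for (i in 1:10) {
    labels <- sample(c(1:4, NA), 40, TRUE)
    a <- count_exchanges(label_painting(labels))$total
    b <- count_exchanges(label_painting(rev(labels)))$total
    expect_equal(a, b)
  }
})

test_that("a genome with no post-ancestor events paints one segment per chromosome", {
  cfg <- new_evolution_config("((A:0.3,B:0.3)anc:0.3,C:0.6)root;", seed = 17,
                              n_chromosomes = 4, genes_per_chromosome = 25)
  sim <- simulate_evolution(cfg)
  p <- paint(sim$orders, true_ancestor(sim, "anc"), true_families(sim),
             genome_id = "A", min_segment = 1)
  expect_equal(nrow(p), 4L)
  expect_equal(count_exchanges(p)$total, 0L)
})

test_that("each reciprocal translocation adds exactly two painted boundaries", {
  for (t in c(0L, 1L, 3L, 5L)) {
    cfg <- new_evolution_config("(X:1.0,Y:1.0)r;", seed = 23,
                                events = list(X = list(translocations = t)))
    sim <- simulate_evolution(cfg)
    p <- paint(sim$orders, true_ancestor(sim, "r"), true_families(sim),
               genome_id = "X", min_segment = 1)
    expect_equal(count_exchanges(p)$total, 2L * t)
  }
})

test_that("exchanges against the nearer ancestor do not exceed the farther one", {
  worse <- 0L
  for (s in 1:20) {
    ev <- list(anc2 = list(translocations = 3L, inversions = 2L),
               V = list(translocations = 2L, inversions = 2L))
    cfg <- new_evolution_config(
      "(((V:0.2,W:0.2)anc2:0.3,X:0.5)anc1:0.3,Y:0.8)root;",
      seed = 300 + s, events = ev, n_chromosomes = 5,
      genes_per_chromosome = 40)
    sim <- simulate_evolution(cfg)
    tf <- true_families(sim)
    near <- count_exchanges(paint(sim$orders, true_ancestor(sim, "anc2"), tf,
                                  genome_id = "V", min_segment = 1))$total
    far <- count_exchanges(paint(sim$orders, true_ancestor(sim, "anc1"), tf,
                                 genome_id = "V", min_segment = 1))$total
    if (near > far) worse <- worse + 1L
  }
  expect_lte(worse, 2L)
})
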