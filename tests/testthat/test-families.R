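make_pairs <- function(a, b) {
  n <- length(a)
  as_homolog_pairs(data.frame(gene_a = a, gene_b = b, ks = rep(0.5, n),
                              similarity = rep(80, n),
                              pair_class = rep("ortholog", n)))
}

test_that("families are the transitive closure of homology", {
  fam <- build_families(make_pairs(c("a", "b"), c("b", "c")))
  expect_equal(nrow(fam$families), 1L)
  expect_setequal(fam$membership$gene_id, c("a", "b", "c"))
  expect_equal(unique(fam$membership$family_id), "a")  # smallest member

  fam2 <- build_families(make_pairs(c("a", "c"), c("b", "d")))
  expect_equal(nrow(fam2$families), 2L)
  expect_setequal(fam2$families$family_id, c("a", "c"))
})

test_that("families partition the paired-gene set", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:60)
  pr <- data.frame(a = sample(genes, 80, TRUE), b = sample(genes, 80, TRUE))
  pr <- pr[pr$a != pr$b, ]
  fam <- build_families(make_pairs(pr$a, pr$b))
  paired <- unique(c(pr$a, pr$b))
  expect_setequal(fam$membership$gene_id, paired)
  expect_false(anyDuplicated(fam$membership$gene_id) > 0)
})

test_that("a 12-copy star in one genome is one family flagged oversize", {
  genes <- sprintf("s%02d", 1:12)
  g <- toy_orders(genes)                       # all 12 copies in genome G
  fam <- build_families(make_pairs(rep(genes[1], 11), genes[-1]),
                        genomes = g, max_copies_per_genome = 5)
  expect_equal(nrow(fam$families), 1L)
  expect_true(fam$families$oversize)
  # oversize families are masked out of the inference map
  expect_true(all(is.na(family_map(fam)[genes])))
  expect_false(anyNA(family_map(fam, drop_oversize = FALSE)[genes]))
})

test_that("empty pair list gives an empty family set", {
  fam <- build_families(make_pairs(character(0), character(0)))
  expect_equal(nrow(fam$families), 0L)
})

test_that("window adjacencies: w=2 gives neighbors, w=3 adds distance-2 pairs", {
  g <- toy_orders(c("A", "B", "C"))
  fam <- identity_families(c("A", "B", "C"))
  a2 <- extract_generalized_adjacencies(g, fam, w = 2)
  expect_equal(nrow(a2), 2L)
  expect_setequal(paste(a2$gene_a, a2$gene_b), c("A B", "B C"))
  # all + strand: facing ends are 3' of the left gene, 5' of the right gene
  expect_true(all(a2$side_a == 1L & a2$side_b == 0L))

  a3 <- extract_generalized_adjacencies(g, fam, w = 3)
  expect_equal(nrow(a3), 3L)
  expect_true(any(a3$gene_a == "A" & a3$gene_b == "C" & a3$distance == 2L))
})

test_that("strand resolves which ends face each other", {
  g <- toy_orders(c("A", "B"), strands = c("-", "-"))
  fam <- identity_families(c("A", "B"))
  a <- extract_generalized_adjacencies(g, fam, w = 2)
  expect_equal(a$side_a, 0L)  # minus-strand left gene faces right via its 5'
  expect_equal(a$side_b, 1L)
})

test_that("adjacency count on an intact chromosome follows the window law", {
  g <- toy_orders(sprintf("g%02d", 1:20))
  fam <- identity_families(sprintf("g%02d", 1:20))
  a <- extract_generalized_adjacencies(g, fam, w = 7)
  expect_equal(nrow(a), sum(20 - 1:6))  # 99
  expect_equal(nrow(a), 99L)

  set.seed(31)
  for (i in 1:8) {
    n <- sample(8:40, 1)
    w <- sample(2:7, 1)
    genes <- sprintf("x%03d", seq_len(n))
    aa <- extract_generalized_adjacencies(toy_orders(genes),
                                          identity_families(genes), w = w)
    expect_equal(nrow(aa), sum(n - seq_len(w - 1L)))
    # brute-force oracle: enumerate pairs with rank distance <= w-1
    expect_equal(nrow(aa), sum(outer(1:n, 1:n, function(i, j)
      j > i & j - i <= w - 1)))
  }
})

test_that("short inversions keep every neighbor adjacency inside the window", {
  genes <- sprintf("y%02d", 1:15)
  fam <- identity_families(genes)
  keypair <- function(a) unique(paste(pmin(a$family_a, a$family_b),
                                      pmax(a$family_a, a$family_b)))
  before <- extract_generalized_adjacencies(toy_orders(genes), fam, w = 7)
  neighbors <- keypair(before[before$distance == 1L, ])
  # invert genes 5..8 (length 4 < w): displaced neighbors stay within reach
  inv <- genes
  inv[5:8] <- rev(inv[5:8])
  st <- rep("+", 15); st[5:8] <- "-"
  after <- extract_generalized_adjacencies(toy_orders(inv, st), fam, w = 7)
  expect_true(all(neighbors %in% keypair(after)))
  # reading direction is not preserved: some end sides flip
  shared <- merge(before, after, by = c("gene_a", "gene_b"))
  expect_true(any(shared$side_a.x != shared$side_a.y |
                    shared$side_b.x != shared$side_b.y))
})

test_that("tandem same-family pairs are excluded unless requested", {
  g <- toy_orders(c("t1", "t2", "u1"))
  fam <- build_families(make_pairs("t1", "t2"), genomes = g)
  a <- extract_generalized_adjacencies(g, fam, w = 3)
  expect_false(any(a$tandem))
  a2 <- extract_generalized_adjacencies(g, fam, w = 3, include_tandem = TRUE)
  expect_true(any(a2$tandem))
  # unassigned families (u1 has no homolog) never appear
  expect_false(any(c(a$gene_a, a$gene_b) == "u1"))
})

test_that("window size below 2 is rejected", {
  g <- toy_orders(c("A", "B"))
  expect_error(extract_generalized_adjacencies(g, identity_families(c("A", "B")),
                                               w = 1), "w must be >= 2")
})
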