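# a tight peak_set centered on m (half-height interval +- r)
tight_peak <- function(m, r = 0.02, axis = "ks") {
  structure(list(axis = axis,
                 peaks = data.frame(mode = m, lo = m - r, hi = m + r,
                                    mass = 1),
                 n = 100L, bandwidth = 0.01), class = "peak_set")
}

test_that("rooted binary topology counts follow the double factorial", {
  for (n in 3:7) {
    want <- prod(seq(2 * n - 3, 1, by = -2))
    expect_length(enumerate_rooted_topologies(letters[1:n]), want)
  }
  expect_error(enumerate_rooted_topologies(letters[1:9]), "limited to 8")
})

test_that("enumerated topologies are distinct canonical newicks", {
  tp <- enumerate_rooted_topologies(c("A", "B", "C", "D"))
  expect_false(anyDuplicated(names(tp)) > 0)
  expect_true(all(grepl("^\\(.*\\);$", names(tp))))
})

test_that("three leaves with one younger pair admit exactly one topology", {
  pp <- list("A|B" = tight_peak(0.3),
             "A|C" = tight_peak(0.6),
             "B|C" = tight_peak(0.6))
  v <- trees_in_peaks(pp)
  expect_equal(nrow(v), 3L)
  expect_equal(sum(v$consistent), 1L)
  expect_equal(v$topology[v$consistent], "((A,B),C);")
  expect_true(all(v$n_violations[!v$consistent] > 0))
})

test_that("identical wide peaks leave every topology consistent", {
  prs <- c("A|B", "A|C", "A|D", "B|C", "B|D", "C|D")
  pp <- lapply(stats::setNames(prs, prs), function(.) tight_peak(0.5, r = 0.4))
  v <- trees_in_peaks(pp)
  expect_equal(nrow(v), 15L)
  expect_true(all(v$consistent))
})

test_that("the similarity axis mirrors Ks verdicts", {
  ks_modes <- c("A|B" = 0.3, "A|C" = 0.6, "B|C" = 0.6)
  pp_ks <- lapply(ks_modes, tight_peak)
  pp_sim <- lapply(ks_modes, function(m)
    tight_peak(100 - 50 * m, r = 1, axis = "similarity"))
  v1 <- trees_in_peaks(pp_ks, axis = "ks")
  v2 <- trees_in_peaks(pp_sim, axis = "similarity")
  expect_equal(v1$consistent, v2$consistent)
})

test_that("a missing pair peak is a hard error naming the pair", {
  pp <- list("A|B" = tight_peak(0.3), "A|C" = tight_peak(0.6))
  expect_error(trees_in_peaks(pp, leaves = c("A", "B", "C")), "B\\|C")
})

test_that("clock simulations recover the generating four-taxon topology", {
  hits <- 0L
  for (s in 1:8) {
    cfg <- new_evolution_config(
      "(((A:0.2,B:0.2)x:0.3,C:0.5)y:0.4,D:0.9)r;", seed = 400 + s,
      n_chromosomes = 2, genes_per_chromosome = 80)
    sim <- simulate_evolution(cfg)
    gmap <- stats::setNames(sim$orders$genome, sim$orders$gene_id)
    ga <- gmap[sim$pairs$gene_a]; gb <- gmap[sim$pairs$gene_b]
    ok <- ga != gb & sim$pairs$pair_class == "ortholog"
    key <- paste(pmin(ga, gb), pmax(ga, gb), sep = "|")
    pp <- lapply(split(sim$pairs$ks[ok], key[ok]), estimate_peaks)
    v <- trees_in_peaks(pp)
    if (sum(v$consistent) == 1L &&
        v$topology[v$consistent] == "(((A,B),C),D);") hits <- hits + 1L
  }
  expect_equal(hits, 8L)
})

test_that("paralog WGD peaks can veto topologies that place them too deep", {
  pp <- list("A|B" = tight_peak(0.3),
             "A|C" = tight_peak(0.6),
             "B|C" = tight_peak(0.6))
  # WGD on A younger than every node: no extra constraint violated
  v1 <- trees_in_peaks(pp, use_paralog_peaks = TRUE,
                       paralog_peaks = list(A = tight_peak(0.1)))
  expect_equal(sum(v1$consistent), 1L)
  # WGD on A older than the root: everything inconsistent
  v2 <- trees_in_peaks(pp, use_paralog_peaks = TRUE,
                       paralog_peaks = list(A = tight_peak(0.9)))
  expect_equal(sum(v2$consistent), 0L)
})
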