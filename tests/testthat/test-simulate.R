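test_that("a single branch with no events copies the root genome", {
  cfg <- new_evolution_config("(A:0.4,B:0.4)r;", seed = 2,
                              n_chromosomes = 2, genes_per_chromosome = 20)
  sim <- simulate_evolution(cfg)
  a <- sim$orders[sim$orders$genome == "A", ]
  root <- true_ancestor(sim, "r")
  expect_equal(nrow(a), 40L)
  # same family sequence per chromosome as the root
  fm <- sim$truth$family_map
  expect_equal(unname(fm[a$gene_id[a$chromosome == "chr01"]]),
               root$family_id[root$protochromosome_id == 1])
  # ortholog Ks clusters around the path length through the root (0.8)
  expect_lt(abs(mean(sim$pairs$ks) - 0.8), 3 * 0.05 / sqrt(nrow(sim$pairs)) + 0.01)
})

test_that("a WGD without fractionation doubles the genome", {
  cfg <- new_evolution_config("(A:0.4,B:0.4)r;", seed = 3,
                              events = list(A = list(wgd = 1L)),
                              n_chromosomes = 2, genes_per_chromosome = 20)
  sim <- simulate_evolution(cfg)
  a <- sim$orders[sim$orders$genome == "A", ]
  expect_equal(nrow(a), 80L)
  fm <- sim$truth$family_map
  expect_true(all(table(fm[a$gene_id]) == 2L))
  # paralog Ks anchors at twice the distance from the WGD (mid-branch) to tip
  par <- sim$pairs[sim$pairs$pair_class == "paralog", ]
  expect_gt(nrow(par), 0L)
  expect_lt(abs(mean(par$ks) - 2 * 0.2), 0.02)
})

test_that("fractionation deletes the expected share of duplicate copies", {
  cfg <- new_evolution_config("(A:0.4,B:0.4)r;", seed = 5,
                              events = list(A = list(wgd = 1L,
                                                     fractionation = 0.2)),
                              n_chromosomes = 7, genes_per_chromosome = 150)
  sim <- simulate_evolution(cfg)
  n_dup <- 1050L
  retained <- nrow(sim$orders[sim$orders$genome == "A", ]) - n_dup
  se <- sqrt(n_dup * 0.2 * 0.8)
  expect_lt(abs(retained - 0.8 * n_dup), 3 * se)
})

test_that("gene counts are conserved up to WGD multipliers and deletions", {
  ev <- list(A = list(wgd = 1L, addition = 1L, fractionation = 0.3,
                      inversions = 4L, translocations = 2L,
                      fusions = 1L, fissions = 1L))
  cfg <- new_evolution_config("(A:0.4,B:0.4)r;", seed = 7, events = ev,
                              n_chromosomes = 3, genes_per_chromosome = 30)
  sim <- simulate_evolution(cfg)
  deleted <- sum(vapply(sim$truth$event_log, function(e)
    if (identical(e$type, "fractionation")) length(e$deleted) else 0L, 0L))
  nA <- nrow(sim$orders[sim$orders$genome == "A", ])
  expect_equal(nA, 90L * 3L - deleted)   # x2 (WGD) then +1 subgenome
})

test_that("ortholog Ks matches the tree path length within clock noise", {
  cfg <- new_evolution_config("((A:0.3,B:0.3)anc:0.3,C:0.6)root;", seed = 11,
                              n_chromosomes = 2, genes_per_chromosome = 40)
  sim <- simulate_evolution(cfg)
  gmap <- stats::setNames(sim$orders$genome, sim$orders$gene_id)
  key <- paste(gmap[sim$pairs$gene_a], gmap[sim$pairs$gene_b])
  mn <- tapply(sim$pairs$ks, key, mean)
  nn <- tapply(sim$pairs$ks, key, length)
  want <- c("A B" = 0.6, "A C" = 1.2, "B C" = 1.2)
  for (k in names(want))
    expect_lt(abs(mn[[k]] - want[[k]]), 3 * 0.05 / sqrt(nn[[k]]) + 0.01)
})

test_that("simulations are deterministic and the event log replays exactly", {
  cfg <- preset_eudicot(seed = 37, genes_per_chromosome = 40)
  s1 <- simulate_evolution(cfg)
  s2 <- simulate_evolution(cfg)
  expect_identical(s1$orders, s2$orders)
  expect_identical(s1$pairs, s2$pairs)
  s3 <- replay_events(cfg, s1$truth$event_log)
  expect_identical(s1$orders, s3$orders)
  expect_identical(s1$truth$node_orders, s3$truth$node_orders)
})

test_that("the eudicot preset carries the expected ploidy signature", {
  sim <- simulate_evolution(preset_eudicot(seed = 19))
  fm <- sim$truth$family_map
  modal_copies <- function(g) {
    cc <- table(table(fm[sim$orders$gene_id[sim$orders$genome == g]]))
    as.integer(names(cc)[which.max(cc)])
  }
  expect_equal(modal_copies("ran"), 1L)
  expect_equal(modal_copies("bux"), 2L)
  expect_equal(modal_copies("tet"), 4L)
  expect_equal(modal_copies("coreA"), 3L)
  expect_equal(modal_copies("coreB"), 3L)
})

test_that("configs validate probabilities, seeds and event names", {
  expect_error(new_evolution_config("(A:1,B:1)r;", seed = 1,
                                    events = list(Z = list(wgd = 1L))),
               "unknown branch")
  expect_error(new_evolution_config("(A:1,B:1)r;", seed = 1,
                                    events = list(A = list(fractionation = 2))),
               "\\[0,1\\]")
  expect_error(new_evolution_config("(A:1,B:1)r;"), "seed")
})
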