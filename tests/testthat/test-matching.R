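test_that("heavier edge wins a contested vertex", {
  m <- max_weight_matching(data.frame(u = c("a", "b"), v = c("b", "c"),
                                      w = c(3L, 2L)))
  expect_equal(m[["a"]], "b")
  expect_true(is.na(m[["c"]]))
})

test_that("conflicting ends: two light adjacencies beat one heavy one", {
  # a.1 is contested by {a,b} (w3) and {a,c} (w2); b.0 by {a,b} and {b,c}.
  # Taking the two w2 edges (total 4) beats the single w3 edge.
  ed <- data.frame(u = c("a.1", "a.1", "b.0"), v = c("b.0", "c.0", "c.1"),
                   w = c(3L, 2L, 2L))
  m <- max_weight_matching(ed)
  expect_equal(matching_weight(m, ed), 4)
  expect_equal(matching_weight(m, ed), mwm_reference_weight(ed))
  expect_true(is.na(m[["a.1"]]) || m[["a.1"]] == "c.0")
})

test_that("matching is a valid symmetric pairing (each end used at most once)", {
  set.seed(51)
  for (i in 1:25) {
    ed <- random_port_edges()
    m <- max_weight_matching(ed)
    matched <- m[!is.na(m)]
    expect_true(all(vapply(names(matched), function(x) m[[m[[x]]]] == x,
                           TRUE)))
    expect_false(anyDuplicated(matched) > 0)
  }
})

test_that("matched weight equals the exhaustive-search optimum on random instances", {
  set.seed(61)
  agree <- 0L
  for (i in 1:100) {
    ed <- random_port_edges()
    got <- matching_weight(max_weight_matching(ed), ed)
    want <- mwm_reference_weight(ed)
    agree <- agree + (got == want)
  }
  expect_equal(agree, 100L)
})

test_that("matching is deterministic for a fixed edge table", {
  set.seed(71)
  ed <- random_port_edges()
  m1 <- max_weight_matching(ed)
  m2 <- max_weight_matching(ed)
  expect_identical(m1, m2)
})

test_that("degenerate inputs are handled or rejected", {
  expect_error(max_weight_matching(data.frame(u = "a", v = "a", w = 1L)),
               "self-loops")
  expect_error(max_weight_matching(data.frame(u = "a", v = "b", w = 0L)),
               "positive")
  m <- max_weight_matching(data.frame(u = character(0), v = character(0),
                                      w = integer(0)))
  expect_length(m, 0L)
})
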