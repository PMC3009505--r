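test_that("chains and cherries yield the counts forced by the geometry", {
  g3 <- chain_glycan(c("A", "B", "C"), c("b1-4", "b1-3"))
  expect_identical(nrow(enumerate_qgrams(g3, 2)), 2L)
  expect_identical(nrow(enumerate_qgrams(g3, 3)), 1L)
  expect_identical(nrow(enumerate_qgrams(g3, 4)), 0L) # q > node count

  # root with two leaf children: the single 3-subset is a bent path,
  # shape (2,1), apex at layer 0
  ch <- cherry_glycan(c("Man", "Gal", "Xyl"), c("b1-2", "b1-4"))
  occ <- enumerate_qgrams(ch, 3)
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$s1, 2L)
  expect_identical(occ$s2, 1L)
  expect_identical(occ$layer, 0L)
  # straight-only mode drops the bent path
  expect_identical(nrow(enumerate_qgrams(ch, 3, straight_only = TRUE)), 0L)

  expect_error(enumerate_qgrams(g3, 0), class = "glyqgram_argument")
})

test_that("canonical keys collide exactly when labeled structure matches", {
  rep3 <- chain_glycan(c("A", "A", "A"), c("b1-4", "b1-4"))
  expect_identical(attr(qgram_index(list(rep3), 2), "d_q"), 1L)
  dis3 <- chain_glycan(c("A", "B", "C"), c("b1-4", "b1-3"))
  expect_identical(attr(qgram_index(list(dis3), 2), "d_q"), 2L)
  # disjoint alphabets: index sizes add
  g1 <- chain_glycan(c("A", "B"), "b1-4", id = "g1")
  g2 <- chain_glycan(c("X", "Y"), "a1-3", id = "g2")
  d_both <- attr(qgram_index(list(g1, g2), 2), "d_q")
  expect_identical(d_both,
                   attr(qgram_index(list(g1), 2), "d_q") +
                     attr(qgram_index(list(g2), 2), "d_q"))
  expect_identical(attr(qgram_index(list(), 2), "d_q"), 0L)
})

test_that("bent-path canonicalization is invariant to sibling encoding order", {
  # same labeled cherry written with the children swapped in the edge list
  a <- glycan(data.frame(node = 1:3, mono = c("Man", "Gal", "Xyl")),
              data.frame(child = c(2, 3), parent = 1, bond = c("b1-2", "b1-4")))
  b <- glycan(data.frame(node = 1:3, mono = c("Man", "Xyl", "Gal")),
              data.frame(child = c(3, 2), parent = 1, bond = c("b1-2", "b1-4")))
  expect_identical(enumerate_qgrams(a, 3)$key, enumerate_qgrams(b, 3)$key)
})

test_that("count matrix conserves embeddings and honors the unseen-key policy", {
  set.seed(5)
  gs <- generate_glycans(8, small_config(), prefix = "cm")
  idx <- qgram_index(gs, 2)
  X <- qgram_counts(gs, idx)
  expect_identical(dim(X), c(attr(idx, "d_q"), 8L))
  expect_true(all(X >= 0))
  for (s in seq_along(gs)) {
    expect_identical(sum(X[, s]), nrow(enumerate_qgrams(gs[[s]], 2)))
  }
  # multiplicity: repeated 2-gram counted twice
  rep3 <- chain_glycan(c("A", "A", "A"), c("b1-4", "b1-4"), id = "r")
  Xr <- qgram_counts(list(rep3), qgram_index(list(rep3), 2))
  expect_identical(unname(Xr[1, 1]), 2L)
  # column of a glycan with no q-node subtree is all zero
  one <- chain_glycan("Gal", character(), id = "single")
  X1 <- qgram_counts(list(one), idx)
  expect_true(all(X1 == 0L))
  # strict vs extend for out-of-index keys
  novel <- chain_glycan(c("ZZ1", "ZZ2"), "b9-9", id = "novel")
  expect_error(qgram_counts(list(novel), idx), class = "glyqgram_unseen_key")
  Xe <- qgram_counts(list(novel), idx, policy = "extend")
  expect_identical(nrow(Xe), attr(idx, "d_q") + 1L)
  # input order only permutes columns
  X2 <- qgram_counts(rev(gs), idx)
  expect_identical(X2[, colnames(X)], X)
})

test_that("enumeration agrees with the exhaustive connected-subset oracle", {
  # 200 random trees up to 12 nodes, q = 1..5, exact multiset agreement
  set.seed(4242)
  cfg <- generator_config(min_nodes = 2, max_nodes = 12, max_depth = 6,
                          branch_prob = 0.4)
  for (i in 1:200) {
    g <- random_glycan(cfg, id = paste0("o", i))
    for (q in 1:5) {
      got <- sort(enumerate_qgrams(g, q)$key)
      want <- sort(oracle_qgrams(g, q))
      if (!identical(got, want)) {
        fail(sprintf("q-gram mismatch on tree %d (q = %d):\n%s", i, q,
                     write_kcf(g)))
      }
    }
  }
  succeed()
})

test_that("representative layer is the corpus mode with ties to the smaller", {
  # the A-B 2-gram occurs at layer 1 twice and layer 0 once -> mode 1
  gA <- chain_glycan(c("X", "A", "B"), c("a1-1", "b1-4"), id = "A")
  gA2 <- chain_glycan(c("Y", "A", "B"), c("a1-2", "b1-4"), id = "A2")
  gB <- chain_glycan(c("A", "B"), "b1-4", id = "B")
  idx <- qgram_index(list(gA, gA2, gB), 2)
  key <- "2|2,0|A;B|b1-4"
  expect_identical(idx$layer[idx$key == key], 1L)
  # tie between layers 0 and 1 resolves to 0
  idx2 <- qgram_index(list(gB, chain_glycan(c("X", "A", "B"),
                                            c("a1-1", "b1-4"), id = "C")), 2)
  expect_identical(idx2$layer[idx2$key == key], 0L)
})
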