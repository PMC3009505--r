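test_that("layer similarity is 1 at zero distance and decays as 1/(1+d)", {
  expect_equal(layer_similarity(3, 3), 1)
  expect_equal(layer_similarity(2, 3), 0.5)
  expect_equal(layer_similarity(0, 4), 0.2)
  expect_equal(layer_similarity(4, 0), layer_similarity(0, 4))
  expect_error(layer_similarity(-1, 2), class = "glyqgram_argument")
})

test_that("bond similarity reproduces the shipped table with fallbacks", {
  expect_equal(bond_similarity("b1-4", "b1-3"), 0.9)
  expect_equal(bond_similarity("b1-3", "b1-4"), 0.9) # symmetrized
  expect_equal(bond_similarity("-4", "a1-4"), 0.8)
  expect_equal(bond_similarity("b1-4", "b1-4"), 1)
  expect_equal(bond_similarity("a2-6", "a2-8"), 0.7)
  # fallbacks: unlisted identical -> 1, unlisted distinct -> 0, wildcard -> 1
  expect_equal(bond_similarity("b9-9", "b9-9"), 1)
  expect_equal(bond_similarity("b9-9", "b1-4"), 0)
  expect_equal(bond_similarity("*", "a2-3"), 1)
  tb <- bond_similarity_table()
  expect_true(all(tb >= 0 & tb <= 1))
  expect_identical(tb, t(tb))
  expect_true(all(diag(tb) == 1))
})

test_that("mono similarity defaults to identity and honors a user table", {
  expect_equal(mono_similarity("Gal", "Gal"), 1)
  expect_equal(mono_similarity("Gal", "Neu5Ac"), 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tGal\tGlc", "Gal\t1\t0.7", "Glc\t0.7\t1"), path)
  tab <- mono_similarity_table(path)
  expect_equal(mono_similarity("Gal", "Glc", table = tab), 0.7)
  expect_equal(mono_similarity("Fruf", "Fruf", table = tab), 1)
  expect_equal(mono_similarity("Fruf", "Gal", table = tab), 0)
})

test_that("shape gating zeroes similarity between straight and bent q-grams", {
  straight <- enumerate_qgrams(
    chain_glycan(c("Man", "Gal", "Xyl"), c("b1-2", "b1-4")), 3)
  bent <- enumerate_qgrams(
    cherry_glycan(c("Man", "Gal", "Xyl"), c("b1-2", "b1-4")), 3)
  expect_identical(c(straight$s1, straight$s2), c(3L, 0L))
  expect_identical(c(bent$s1, bent$s2), c(2L, 1L))
  expect_identical(lk_similarity(straight, bent), 0)
})

test_that("lk similarity multiplies layer, residue and bond components", {
  a <- enumerate_qgrams(chain_glycan(c("Gal", "GlcNAc"), "b1-4"), 2)
  b <- enumerate_qgrams(chain_glycan(c("Gal", "GlcNAc"), "b1-3"), 2)
  # same layer, identical monos, bonds 0.9 apart
  expect_equal(lk_similarity(a, b), 0.9)
  expect_equal(lk_similarity(a, a), 1)
  # a layer step halves it under the default 1/(1+d)
  b_shift <- b
  b_shift$layer <- 1L
  expect_equal(lk_similarity(a, b_shift), 0.45)
  # mismatched q is a usage error
  c1 <- enumerate_qgrams(chain_glycan(c("Gal", "GlcNAc", "Man"),
                                      c("b1-4", "b1-2")), 3)
  expect_error(lk_similarity(a, c1), class = "glyqgram_argument")
})

test_that("lk similarity is symmetric, bounded, and degrades monotonically", {
  set.seed(88)
  gs <- generate_glycans(10, small_config())
  idx <- qgram_index(gs, 3)
  n <- min(nrow(idx), 15L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sij <- lk_similarity(idx[i, ], idx[j, ])
      expect_gte(sij, 0)
      expect_lte(sij, 1)
      expect_identical(sij, lk_similarity(idx[j, ], idx[i, ]))
    }
  }
  # with identity tables and equal layers, similarity 1 iff same key
  for (i in seq_len(n)) {
    a <- as.list(idx[i, ])
    a$monos <- a$monos[[1]]; a$bonds <- a$bonds[[1]]
    for (j in seq_len(n)) {
      b <- as.list(idx[j, ])
      b$monos <- b$monos[[1]]; b$bonds <- b$bonds[[1]]
      b$layer <- a$layer
      s <- lk_similarity(a, b, bond_table = matrix(nrow = 0, ncol = 0))
      expect_identical(s == 1, a$key == b$key)
    }
  }
  # replacing one matched bond pair by a lower-scoring pair cannot increase it
  base <- list(q = 3L, s1 = 3L, s2 = 0L, layer = 1L,
               monos = c("Gal", "GlcNAc", "Man"), bonds = c("b1-4", "a1-3"))
  other <- base
  other$bonds <- c("b1-3", "a1-3") # 0.9 against b1-4
  worse <- base
  worse$bonds <- c("a2-3", "a1-3") # 0.4 against b1-4
  expect_gt(lk_similarity(base, other), lk_similarity(base, worse))
})

test_that("lk matrix is symmetric with unit diagonal and gated off-diagonals", {
  set.seed(12)
  gs <- generate_glycans(6, small_config())
  idx <- qgram_index(gs, 2)
  S <- lk_matrix(idx)
  expect_identical(dim(S), c(nrow(idx), nrow(idx)))
  expect_equal(unclass(S), t(unclass(S)))
  expect_true(all(diag(S) == 1))
  # single-entry index gives [[1]]
  idx1 <- qgram_index(list(chain_glycan(c("A", "B"), "b1-4")), 2)
  expect_equal(unclass(lk_matrix(idx1)), matrix(1, 1, 1,
               dimnames = list(idx1$key, idx1$key)), ignore_attr = TRUE)
  # straight vs bent entries are zero by the shape gate
  mix <- qgram_index(list(chain_glycan(c("A", "B", "C"), c("b1-4", "b1-4")),
                          cherry_glycan(c("A", "B", "C"), c("b1-4", "b1-4"))), 3)
  Smix <- lk_matrix(mix)
  stra <- mix$s2 == 0L
  expect_true(all(Smix[stra, !stra] == 0))
})
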