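test_that("psd correction clips negative eigenvalues and reports them", {
  # [[1,2],[2,1]] has eigenvalues 3 and -1; the clipped nearest PSD matrix
  # is [[1.5,1.5],[1.5,1.5]]
  S <- matrix(c(1, 2, 2, 1), 2)
  W <- psd_correct(S)
  rep <- attr(W, "psd_report")
  expect_equal(rep$min_eigen_before, -1)
  expect_gte(rep$min_eigen_after, 0)
  expect_equal(unclass(W), matrix(1.5, 2, 2) + diag(1e-9, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identity passes through (up to the ridge)
  I5 <- diag(5)
  expect_equal(unclass(psd_correct(I5)), I5, tolerance = 1e-6,
               ignore_attr = TRUE)
  # an already-PSD matrix is unchanged within tolerance
  set.seed(3)
  A <- crossprod(matrix(rnorm(25), 5))
  expect_lt(norm(unclass(psd_correct(A)) - A, "F"), 1e-8)
  # diagonal-shift alternative also ends PSD
  Ws <- psd_correct(S, method = "shift")
  expect_gte(attr(Ws, "psd_report")$min_eigen_after, 0)
  expect_equal(Ws[1, 2], 2) # off-diagonals untouched
  expect_error(psd_correct(matrix(c(1, NA, NA, 1), 2)),
               class = "glyqgram_argument")
})

test_that("plain kernel is the count-vector Gram matrix", {
  X <- matrix(c(2, 0, 3, 0), nrow = 1,
              dimnames = list("k1", paste0("g", 1:4)))
  K <- qgram_kernel(X)
  expect_equal(K["g1", "g3"], 6) # (2)(3) on the shared key
  expect_equal(K["g1", "g4"], 0) # disjoint support
  expect_equal(unclass(K), crossprod(X), ignore_attr = TRUE)
  # W = I reduction
  expect_equal(unclass(weighted_kernel(X, diag(1, 1))), unclass(K),
               ignore_attr = TRUE)
})

test_that("weighted kernel computes X'WX and validates dimensions", {
  X <- diag(1, 2)
  dimnames(X) <- list(c("a", "b"), c("g1", "g2"))
  W <- matrix(c(1, 0.9, 0.9, 1), 2)
  K <- weighted_kernel(X, W)
  expect_equal(K["g1", "g2"], 0.9)
  x <- matrix(c(1, 2), ncol = 1)
  expect_equal(as.numeric(weighted_kernel(x, W)), t(x) %*% W %*% x |> as.numeric())
  expect_gte(as.numeric(weighted_kernel(x, W)), 0)
  expect_error(weighted_kernel(X, diag(3)), class = "glyqgram_argument")
})

test_that("kernel combination is the weighted entrywise sum", {
  A <- qgram_kernel(matrix(1:4, 2, dimnames = list(NULL, c("g1", "g2"))))
  B <- qgram_kernel(matrix(c(0, 1, 1, 0), 2,
                           dimnames = list(NULL, c("g1", "g2"))))
  expect_equal(unclass(combine_kernels(list(A, B))), unclass(A) + unclass(B),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(list(A, B), c(0, 1))), unclass(B),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(list(A), 1)), unclass(A),
               ignore_attr = TRUE)
  bad <- qgram_kernel(matrix(1:4, 2, dimnames = list(NULL, c("g9", "g2"))))
  expect_error(combine_kernels(list(A, bad)), class = "glyqgram_argument")
})

test_that("cosine normalization fixes the diagonal and ignores scale", {
  K <- matrix(c(4, 2, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  Kn <- cosine_normalize(K)
  expect_equal(unclass(Kn), matrix(1, 2, 2, dimnames = dimnames(K)),
               ignore_attr = TRUE)
  K2 <- cosine_normalize(7 * K)
  expect_equal(unclass(K2), unclass(cosine_normalize(K)), ignore_attr = TRUE)
  K0 <- matrix(c(0, 0, 0, 1), 2, dimnames = list(c("z1", "z2"), c("z1", "z2")))
  expect_error(cosine_normalize(K0), class = "glyqgram_normalize")
  expect_error(cosine_normalize(K0), "z1")
})

test_that("pipeline kernels are symmetric PSD and satisfy the sum identity", {
  set.seed(61)
  gs <- generate_glycans(15, small_config())
  kernels <- list()
  for (q in 2:4) {
    idx <- qgram_index(gs, q)
    X <- qgram_counts(gs, idx)
    Kq <- qgram_kernel(X)
    expect_silent(check_kernel(Kq))
    kernels[[as.character(q)]] <- Kq
    # weighted variants stay symmetric PSD
    W <- psd_correct(lk_matrix(idx))
    expect_silent(check_kernel(weighted_kernel(X, W)))
  }
  KQ <- combine_kernels(kernels)
  expect_equal(unclass(KQ),
               unclass(kernels[[1]]) + unclass(kernels[[2]]) + unclass(kernels[[3]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_silent(check_kernel(KQ))
})

test_that("forcing the similarity to the identity recovers the plain kernel", {
  set.seed(62)
  gs <- generate_glycans(10, small_config())
  idx <- qgram_index(gs, 2)
  X <- qgram_counts(gs, idx)
  # identity weight through the full PSD path
  W <- psd_correct(diag(1, nrow(idx)))
  expect_equal(unclass(weighted_kernel(X, W)), unclass(qgram_kernel(X)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # LK with an empty bond table (identity fallback) and layer ignored
  S <- lk_matrix(idx, bond_table = matrix(nrow = 0, ncol = 0),
                 layer_formula = function(d) 1)
  expect_equal(unclass(S), diag(1, nrow(idx)), ignore_attr = TRUE)
})

test_that("matrix TSV round-trip preserves labels and values", {
  set.seed(63)
  gs <- generate_glycans(4, small_config())
  K <- qgram_kernel(qgram_counts(gs, qgram_index(gs, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(K, path)
  back <- read_matrix_tsv(path)
  expect_equal(back, unclass(K), ignore_attr = TRUE)
  expect_identical(colnames(back), colnames(K))
})
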