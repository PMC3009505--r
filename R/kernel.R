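#' Correct a similarity matrix to positive semidefiniteness
#'
#' A raw inter-q-gram similarity matrix (from alignment scores or graded
#' label similarity) need not be positive semidefinite, but the weight
#' matrix of a weighted q-gram kernel must be, or `X' W X` is not a valid
#' kernel.  The correction symmetrizes, eigendecomposes, clips negative
#' eigenvalues to zero (the nearest PSD matrix in Frobenius norm) and adds
#' a tiny ridge.  Alternatively `method = "shift"` adds `|lambda_min| I`
#' when the minimum eigenvalue is negative, preserving off-diagonal
#' structure exactly at the cost of inflating the diagonal.
#'
#' @param S A square finite numeric matrix.
#' @param method `"clip"` (default) or `"shift"`.
#' @param ridge Ridge added to the diagonal after correction.
#' @return A `weight_matrix`: the corrected matrix with attribute
#'   `psd_report`, a list recording the method, the minimum eigenvalue
#'   before and after, and the ridge used.
#' @export
psd_correct <- function(S, method = c("clip", "shift"), ridge = 1e-9) {
  method <- match.arg(method)
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    abort("S must be a square matrix", class = "glyqgram_argument")
  }
  if (any(!is.finite(S))) {
    abort("S contains non-finite entries", class = "glyqgram_argument")
  }
  dn <- dimnames(S)
  A <- (S + t(S)) / 2
  if (nrow(A) == 0L) {
    return(structure(A, class = c("weight_matrix", "matrix", "array"),
                     psd_report = list(method = method, min_eigen_before = NA,
                                       min_eigen_after = NA, ridge = ridge)))
  }
  e <- eigen(A, symmetric = TRUE)
  min_before <- min(e$values)
  if (method == "clip") {
    vals <- pmax(e$values, 0)
    W <- e$vectors %*% (vals * t(e$vectors))
  } else {
    W <- A
    if (min_before < 0) W <- W + diag(abs(min_before), nrow(A))
  }
  W <- (W + t(W)) / 2 + diag(ridge, nrow(A))
  min_after <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  dimnames(W) <- dn
  structure(W, class = c("weight_matrix", "matrix", "array"),
            psd_report = list(method = method,
                              min_eigen_before = min_before,
                              min_eigen_after = min_after,
                              ridge = ridge))
}

#' Plain q-gram kernel
#'
#' The inner-product kernel of q-gram count vectors: `K = X'X`, where
#' column `s` of `X` counts the q-gram occurrences of glycan `s`.  Equals
#' [weighted_kernel()] with the identity weight matrix — the classical
#' q-gram method assumes distinct q-grams share no similarity.
#'
#' @param X A count matrix from [qgram_counts()].
#' @return A `glycan_kernel` matrix (n x n, glycan ids as dimnames).
#' @export
qgram_kernel <- function(X) {
  K <- crossprod(X)
  new_glycan_kernel(K, method = "qgram", q = attr(X, "q"))
}

#' Weighted q-gram kernel
#'
#' `K = X' W X`: the weighted q-gram kernel, in which the (PSD) weight
#' matrix `W` injects inter-q-gram similarity so that glycans sharing
#' *similar* — not only identical — substructures obtain kernel credit.
#' With `W = I` this reduces exactly to the plain q-gram kernel.
#'
#' @param X A count matrix (`d_q x n`).
#' @param W A `d_q x d_q` weight matrix, typically from [psd_correct()].
#' @return A `glycan_kernel` matrix.
#' @export
weighted_kernel <- function(X, W) {
  if (nrow(W) != nrow(X) || ncol(W) != nrow(X)) {
    abort("weight matrix dimension must equal the count-matrix row count",
          class = "glyqgram_argument")
  }
  K <- t(X) %*% W %*% X
  K <- (K + t(K)) / 2
  new_glycan_kernel(K, method = paste0("weighted:",
                                       attr(W, "psd_report")$method %||% "custom"))
}

#' Combine kernels across q
#'
#' Computes the weighted sum `sum_q alpha_q K_q`.  With unnormalized unit
#' weights this is exactly the Q-gram kernel `K_Q = sum_q K_q`; with
#' weights from [mkl_weights()] it is the multiple-kernel combination.
#'
#' @param kernels A list of kernel matrices over the same glycans in the
#'   same order.
#' @param weights Numeric vector of non-negative weights, recycled to the
#'   number of kernels; default all 1.
#' @return A `glycan_kernel` matrix.
#' @export
combine_kernels <- function(kernels, weights = NULL) {
  stopifnot(length(kernels) >= 1L)
  ids <- colnames(kernels[[1]])
  for (K in kernels) {
    if (!identical(dim(K), dim(kernels[[1]])) ||
        !identical(colnames(K), ids)) {
      abort("kernels must share dimension and glycan order",
            class = "glyqgram_argument")
    }
  }
  if (is.null(weights)) weights <- rep(1, length(kernels))
  weights <- rep_len(weights, length(kernels))
  if (any(weights < 0)) abort("negative kernel weight", class = "glyqgram_argument")
  out <- matrix(0, nrow(kernels[[1]]), ncol(kernels[[1]]),
                dimnames = dimnames(kernels[[1]]))
  for (i in seq_along(kernels)) out <- out + weights[i] * unclass(kernels[[i]])
  new_glycan_kernel(out, method = "combined", weights = weights)
}

#' Cosine-normalize a kernel
#'
#' Rescales to unit diagonal, `K'_st = K_st / sqrt(K_ss K_tt)`.  Useful
#' before combining kernels across q, whose raw scales grow with the
#' number of q-gram occurrences.
#'
#' @param K A kernel matrix with strictly positive diagonal.
#' @return A `glycan_kernel` with unit diagonal.
#' @export
cosine_normalize <- function(K) {
  d <- diag(K)
  if (any(d <= 0)) {
    bad <- colnames(K)[which(d <= 0)[1]] %||% which(d <= 0)[1]
    abort(paste0("zero diagonal entry for glycan ", bad,
                 "; cannot cosine-normalize"), class = "glyqgram_normalize")
  }
  s <- 1 / sqrt(d)
  new_glycan_kernel(unclass(K) * outer(s, s),
                    method = paste0(attr(K, "method") %||% "kernel", ":cosine"))
}

new_glycan_kernel <- function(K, method = "kernel", q = NULL, weights = NULL) {
  structure(K, class = c("glycan_kernel", "matrix", "array"),
            method = method, q = q, weights = weights)
}

#' Check kernel validity
#'
#' @param K A matrix.
#' @param sym_tol Maximum allowed `|K - K'|`.
#' @param eigen_tol Minimum allowed eigenvalue.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
check_kernel <- function(K, sym_tol = 1e-10, eigen_tol = -1e-8) {
  if (max(abs(K - t(K))) > sym_tol) {
    abort("kernel is not symmetric", class = "glyqgram_kernel")
  }
  ev <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < eigen_tol) {
    abort(sprintf("kernel is not PSD (min eigenvalue %.3g)", ev),
          class = "glyqgram_kernel")
  }
  invisible(TRUE)
}

#' @export
print.glycan_kernel <- function(x, ...) {
  cat("<glycan_kernel> ", ncol(x), " x ", ncol(x),
      ", method = ", attr(x, "method") %||% "?", "\n", sep = "")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Read and write labeled matrices as TSV
#'
#' Serializes kernels, similarity matrices and count matrices with their
#' row/column labels (glycan ids or canonical q-gram keys).
#'
#' @param m A matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  write.table(unclass(m), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, row.names = 1,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d)
  mode(m) <- "numeric"
  m
}
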