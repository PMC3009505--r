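#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic with midrank tie handling: the probability
#' that a random positive outranks a random negative, counting ties as one
#' half.
#'
#' @param scores Numeric decision values, higher meaning more positive.
#' @param labels Labels in `{+1, -1}` (anything coercible: the positive
#'   class is `label > 0`).
#' @return A value in `[0, 1]`.
#' @export
glycan_auc <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present to compute AUC",
          class = "glyqgram_argument")
  }
  r <- rank(scores) # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated cross-validated SVM classification on a precomputed kernel
#'
#' Trains a soft-margin support vector machine on the precomputed glycan
#' kernel and evaluates it by stratified k-fold cross-validation repeated
#' several times: within each repeat the folds are drawn stratified by
#' class (seeded as `seed + repeat`), an SVM is fit on the training block
#' of the kernel, decision values are computed for the held-out block, the
#' AUC is taken per fold, and the repeat's AUC is the mean over its folds.
#' The defaults (5 folds, 50 repeats) match common practice for glycan
#' classification benchmarks.
#'
#' @param K An `n x n` kernel matrix (ids as dimnames).
#' @param labels Named or positional vector of `+1`/`-1` aligned with `K`.
#' @param folds Number of folds, at least 2.
#' @param repeats Number of repetitions of the whole CV.
#' @param cost SVM soft-margin cost `C`.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param tol Stopping tolerance of the SMO solver.  The default 0.1 is
#'   coarser than kernlab's 0.001: decision-value *rankings* — all that AUC
#'   evaluation uses — stabilize long before the KKT conditions are tight,
#'   at a fraction of the cost.  Tighten for decision-value use.
#' @param stratified Draw folds stratified by class (default) or fully at
#'   random.
#' @return A `glycan_cv` object: list with `auc` (overall mean), `sd`
#'   (across repeats), `repeats` (tibble of per-repeat mean AUCs) and the
#'   configuration.  [tidy()] returns the per-repeat table, [glance()] a
#'   one-row summary.
#' @export
cv_auc <- function(K, labels, folds = 5L, repeats = 50L, cost = 1,
                   seed = 1L, stratified = TRUE, tol = 0.1) {
  stopifnot(folds >= 2L, repeats >= 1L, cost > 0)
  n <- ncol(K)
  if (length(labels) != n) {
    abort("labels must align with the kernel", class = "glyqgram_argument")
  }
  if (!is.null(names(labels)) && !is.null(colnames(K))) {
    labels <- labels[colnames(K)]
  }
  # canonical sample order: results do not depend on the storage order of
  # jointly permuted kernels and labels
  if (!is.null(colnames(K)) && !anyDuplicated(colnames(K))) {
    ord <- order(colnames(K), method = "radix")
    K <- unclass(K)[ord, ord]
    labels <- labels[ord]
  }
  y <- ifelse(labels > 0, 1, -1)
  if (min(table(y)) < folds) {
    abort("smallest class has fewer members than folds",
          class = "glyqgram_config")
  }
  per_repeat <- map_dbl(seq_len(repeats), function(r) {
    set.seed(seed + r)
    fold_id <- draw_folds(y, folds, stratified)
    aucs <- map_dbl(seq_len(folds), function(f) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      dec <- svm_decision(K, y, tr, te, cost, tol)
      glycan_auc(dec, y[te])
    })
    mean(aucs)
  })
  structure(list(auc = mean(per_repeat), sd = sd(per_repeat),
                 repeats = tibble(repeat_id = seq_len(repeats),
                                  auc = per_repeat),
                 config = list(folds = folds, repeats = repeats, cost = cost,
                               seed = seed, stratified = stratified, n = n)),
            class = "glycan_cv")
}

draw_folds <- function(y, folds, stratified) {
  n <- length(y)
  fold_id <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold_id <- rep_len(seq_len(folds), n)[sample(n)]
  }
  fold_id
}

# fit a C-SVC on the training block of a precomputed kernel and return
# decision values for the test block, oriented so that larger means more
# positive (orientation checked against the training decision values)
svm_decision <- function(K, y, tr, te, cost, tol = 0.1) {
  ytr <- factor(y[tr], levels = c(-1, 1))
  # rescale by the mean training self-similarity: a constant kernel scale
  # only reparameterizes the SVM but conditions the SMO solver
  s <- mean(diag(unclass(K))[tr])
  if (is.finite(s) && s > 0) K <- unclass(K) / s
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(unclass(K)[tr, tr]),
                       ytr, type = "C-svc", C = cost, scaled = FALSE,
                       tol = tol)
  sv <- kernlab::SVindex(fit)
  dec_tr <- kernlab::predict(
    fit, kernlab::as.kernelMatrix(unclass(K)[tr, tr][, sv, drop = FALSE]),
    type = "decision")[, 1]
  dec_te <- kernlab::predict(
    fit, kernlab::as.kernelMatrix(unclass(K)[te, tr, drop = FALSE][, sv, drop = FALSE]),
    type = "decision")[, 1]
  # ksvm's decision sign depends on internal class coding; orient on train
  if (glycan_auc(dec_tr, y[tr]) < 0.5) dec_te <- -dec_te
  dec_te
}

#' @export
print.glycan_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<glycan_cv> mean AUC = %.4f (sd %.4f) over %d x %d-fold CV, n = %d\n",
              x$auc, x$sd, cfg$repeats, cfg$folds, cfg$n))
  invisible(x)
}

#' @method tidy glycan_cv
#' @export
tidy.glycan_cv <- function(x, ...) x$repeats

#' @method glance glycan_cv
#' @export
glance.glycan_cv <- function(x, ...) {
  tibble(auc = x$auc, sd = x$sd, folds = x$config$folds,
         repeats = x$config$repeats, cost = x$config$cost,
         n = x$config$n, seed = x$config$seed)
}

#' Multiple-kernel weights by centered kernel-target alignment
#'
#' A deterministic multiple-kernel weighting: each kernel's centered
#' alignment with the label kernel `y y'` is computed,
#' `A(K) = <Kc, Yc>_F / (|Kc|_F |Yc|_F)`, negative alignments are floored
#' at zero, and the weights are normalized to sum 1.  If every alignment
#' is non-positive the weights fall back to uniform with a warning.
#'
#' @param kernels A named list of kernel matrices over the same glycans.
#' @param labels Vector of `+1`/`-1` aligned with the kernels.
#' @return A tibble with columns `kernel` and `weight` (summing to 1).
#' @export
mkl_weights <- function(kernels, labels) {
  stopifnot(length(kernels) >= 1L)
  n <- ncol(kernels[[1]])
  y <- ifelse(labels > 0, 1, -1)
  stopifnot(length(y) == n)
  H <- diag(n) - matrix(1 / n, n, n)
  Yc <- H %*% tcrossprod(y) %*% H
  nyc <- sqrt(sum(Yc^2))
  align <- map_dbl(kernels, function(K) {
    Kc <- H %*% unclass(K) %*% H
    nk <- sqrt(sum(Kc^2))
    if (nk == 0 || nyc == 0) return(0)
    sum(Kc * Yc) / (nk * nyc)
  })
  w <- pmax(align, 0)
  if (sum(w) <= 0) {
    warn("all kernel-target alignments non-positive; using uniform weights",
         class = "glyqgram_mkl")
    w <- rep(1, length(kernels))
  }
  w <- w / sum(w)
  tibble(kernel = names(kernels) %||% paste0("K", seq_along(kernels)),
         weight = unname(w), alignment = unname(align))
}
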