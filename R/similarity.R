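#' Layer similarity
#'
#' Similarity between the layers (linkage distances from the root) of two
#' q-grams, a decreasing function of the layer distance.  The default is
#' `1 / (1 + |l_i - l_j|)`: 1 at equal layers, strictly decreasing in the
#' distance, symmetric, and positive semidefinite as a kernel on the
#' integers.
#'
#' @param l_i,l_j Non-negative integer layers (vectorized).
#' @param formula A function of the absolute layer distance returning a
#'   score in `(0, 1]`.
#' @return Scores in `(0, 1]`.
#' @examples
#' layer_similarity(3, 3) # 1
#' layer_similarity(2, 3) # 0.5
#' @export
layer_similarity <- function(l_i, l_j, formula = function(d) 1 / (1 + d)) {
  if (any(l_i < 0) || any(l_j < 0)) {
    abort("layers must be non-negative", class = "glyqgram_argument")
  }
  formula(abs(l_i - l_j))
}

#' Bond similarity lookup
#'
#' Looks the pair up in a [bond_similarity_table()] after symmetrization.
#' Pairs not covered by the table fall back to: 1 for identical labels, 1
#' when either side is the wildcard root bond, 0 for distinct unlisted
#' pairs — conservative choices that keep all scores in `[0, 1]`.
#'
#' @param b_i,b_j Bond labels (vectorized, recycled).
#' @param table A symmetric similarity matrix with bond-label dimnames.
#' @return Scores in `[0, 1]`.
#' @examples
#' bond_similarity("b1-4", "b1-3") # 0.9
#' bond_similarity("-4", "a1-4")   # 0.8
#' @export
bond_similarity <- function(b_i, b_j, table = bond_similarity_table()) {
  pair_similarity(b_i, b_j, table)
}

#' Monosaccharide similarity lookup
#'
#' With the default identity table (`table = NULL`) the score is 1 for
#' equal labels and 0 otherwise.  A graded table (e.g. SIMCOMP-derived
#' scores loaded with [mono_similarity_table()]) is consulted first;
#' identical labels score 1 even when unlisted, distinct unlisted pairs
#' score 0.
#'
#' @param m_i,m_j Monosaccharide labels (vectorized, recycled).
#' @param table A symmetric similarity matrix, or `NULL` for identity.
#' @return Scores in `[0, 1]`.
#' @export
mono_similarity <- function(m_i, m_j, table = NULL) {
  if (is.null(table)) return(as.numeric(m_i == m_j))
  pair_similarity(m_i, m_j, table, wildcard = NULL)
}

pair_similarity <- function(x, y, table, wildcard = WILDCARD_BOND) {
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  out <- numeric(n)
  labs <- rownames(table)
  listed <- x %in% labs & y %in% labs
  if (any(listed)) out[listed] <- table[cbind(x[listed], y[listed])]
  out[!listed & x == y] <- 1
  if (!is.null(wildcard)) out[x == wildcard | y == wildcard] <- 1
  out
}

#' Linkage (LK) similarity between two q-grams
#'
#' Two q-grams of the same `q` but different canonical shapes are treated
#' as totally different (similarity 0).  For q-grams of equal shape, the
#' similarity combines their layer similarity, the similarities of the
#' monosaccharides at corresponding canonical positions, and the
#' similarities of the bonds at corresponding positions:
#'
#' \deqn{S_q(i,j) = S^l(l^i, l^j) \prod_{k=1}^{q} S^m(m^i_k, m^j_k)
#'   \prod_{k=1}^{q-1} S^b(b^i_k, b^j_k)}
#'
#' The multiplicative combination means any completely dissimilar
#' component annihilates the match, consistent with the shape gate; a mean
#' combination is available via `combine = "mean"`.  Positions are matched
#' by the canonical chain order fixed at enumeration time; chains are never
#' re-matched here.
#'
#' @param a,b Q-grams: rows of a [qgram_index()] (as one-row data frames or
#'   lists with fields `q`, `s1`, `s2`, `layer`, `monos`, `bonds`).
#' @param mono_table,bond_table,layer_formula Component similarity
#'   sources; see [mono_similarity()], [bond_similarity()],
#'   [layer_similarity()].
#' @param combine `"product"` (default) or `"mean"` of the component
#'   scores.
#' @return A score in `[0, 1]` for tables with range `[0, 1]`.
#' @export
lk_similarity <- function(a, b, mono_table = NULL,
                          bond_table = bond_similarity_table(),
                          layer_formula = function(d) 1 / (1 + d),
                          combine = c("product", "mean")) {
  combine <- match.arg(combine)
  a <- as_qgram_fields(a)
  b <- as_qgram_fields(b)
  if (a$q != b$q) abort("q-grams of different q", class = "glyqgram_argument")
  if (a$s1 != b$s1 || a$s2 != b$s2) return(0)
  parts <- c(layer_similarity(a$layer, b$layer, formula = layer_formula),
             mono_similarity(a$monos, b$monos, table = mono_table),
             if (a$q > 1L) bond_similarity(a$bonds, b$bonds, table = bond_table))
  if (combine == "product") prod(parts) else mean(parts)
}

as_qgram_fields <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- list(key = if ("key" %in% names(x)) x$key else NULL,
              q = x$q, s1 = x$s1, s2 = x$s2, layer = x$layer,
              monos = x$monos[[1]], bonds = x$bonds[[1]])
  }
  x
}

#' Build a q-gram similarity matrix
#'
#' Computes the `d_q x d_q` matrix of pairwise q-gram similarities over an
#' index, by the requested method:
#'
#' * `"lk"` — Linkage similarity ([lk_similarity()]): layer, residue and
#'   bond similarity under a shape gate;
#' * `"km"` — KCaM alignment score of the two q-gram structures under
#'   exact-match node scoring ([kcam_score()] / 100);
#' * `"lkm"` — Linkage KCaM: the same alignment with linkage-weighted node
#'   scoring, crediting partial residue/bond/layer similarity.
#'
#' Each entry's representative layer (corpus mode) stands in for the layer
#' of that q-gram.  The result is symmetric but not necessarily positive
#' semidefinite; pass it through [psd_correct()] before building a
#' weighted kernel.
#'
#' @param index A [qgram_index()].
#' @param method `"lk"`, `"km"` or `"lkm"`.
#' @inheritParams lk_similarity
#' @param gap_penalty Gap penalty for the alignment methods.
#' @return A symmetric numeric matrix with q-gram keys as dimnames and
#'   attribute `method`.
#' @export
qgram_similarity <- function(index, method = c("lk", "km", "lkm"),
                             mono_table = NULL,
                             bond_table = bond_similarity_table(),
                             layer_formula = function(d) 1 / (1 + d),
                             combine = c("product", "mean"),
                             gap_penalty = 0) {
  method <- match.arg(method)
  combine <- match.arg(combine)
  d <- nrow(index)
  S <- matrix(0, d, d, dimnames = list(index$key, index$key))
  if (d == 0L) return(structure(S, method = method))
  entries <- map(seq_len(d), function(i) as_qgram_fields(index[i, ]))
  if (method == "lk") {
    for (i in seq_len(d)) {
      S[i, i] <- lk_similarity(entries[[i]], entries[[i]],
                               mono_table = mono_table,
                               bond_table = bond_table,
                               layer_formula = layer_formula,
                               combine = combine)
      if (i < d) for (j in (i + 1L):d) {
        s <- lk_similarity(entries[[i]], entries[[j]],
                           mono_table = mono_table, bond_table = bond_table,
                           layer_formula = layer_formula, combine = combine)
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  } else {
    trees <- map(entries, qgram_as_glycan)
    node_score <- if (method == "km") "exact" else "linkage"
    selfs <- map_dbl(trees, function(tr) {
      kcam_align(tr, tr, node_score = node_score, mono_table = mono_table,
                 bond_table = bond_table, layer_formula = layer_formula,
                 gap_penalty = gap_penalty)$raw
    })
    for (i in seq_len(d)) {
      S[i, i] <- 1
      if (i < d) for (j in (i + 1L):d) {
        raw <- kcam_align(trees[[i]], trees[[j]], node_score = node_score,
                          mono_table = mono_table, bond_table = bond_table,
                          layer_formula = layer_formula,
                          gap_penalty = gap_penalty)$raw
        s <- normalize_alignment(raw, selfs[i], selfs[j]) / 100
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  }
  structure(S, method = method)
}
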