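#' KCaM-style approximate tree alignment of two glycans
#'
#' Dynamic-programming alignment of two rooted labeled trees in the style
#' of the KEGG Carbohydrate Matcher: node pairs score `w(u, v)` and the
#' recursion allows skipping a node of either tree at a (default-free) gap
#' penalty,
#'
#' \deqn{Q(u,v) = \max\{\, w(u,v) + \max_{\phi} \sum_{c} Q(c, \phi(c)),\;
#'   \max_{c_u} Q(c_u, v) - gap,\; \max_{c_v} Q(u, c_v) - gap \,\}}
#'
#' where `phi` ranges over injective assignments of the children of `u` to
#' the children of `v`, solved exactly by exhaustive enumeration (at most
#' `4!` cases at glycan branching).  In `"global"` mode the score is read
#' at the root pair; in `"local"` mode the recursion is floored at 0 and
#' the score is the maximum over all node pairs.
#'
#' Node scoring:
#' * `"exact"` — `w(u,v) = 1` when the monosaccharide labels are equal and
#'   the bonds towards the parents are equal (the wildcard root bond
#'   matches any bond), else 0; structure similarity only, no graded
#'   label similarity.
#' * `"linkage"` — `w(u,v) = S^m(m_u, m_v) S^b(b_u, b_v) S^l(l_u, l_v)`,
#'   crediting partial monosaccharide, bond and layer similarity
#'   (the Linkage KCaM scoring).
#'
#' @param s,t Glycans.
#' @param mode `"global"` (default) or `"local"`.
#' @param node_score `"exact"` or `"linkage"`.
#' @param gap_penalty Non-negative penalty for skipping a node; default 0
#'   (skips are free, as in approximate matching).
#' @param mono_table,bond_table,layer_formula Component similarities for
#'   `"linkage"` scoring.
#' @return A list with `raw` (optimal score, >= 0), `pairs` (tibble of
#'   aligned node pairs `node_s`, `node_t` recovered by traceback).
#' @seealso [kcam_score()] for the 0-100 normalized score.
#' @export
kcam_align <- function(s, t, mode = c("global", "local"),
                       node_score = c("exact", "linkage"),
                       gap_penalty = 0,
                       mono_table = NULL,
                       bond_table = bond_similarity_table(),
                       layer_formula = function(d) 1 / (1 + d)) {
  mode <- match.arg(mode)
  node_score <- match.arg(node_score)
  stopifnot(gap_penalty >= 0)
  if (nrow(s$nodes) == 0L || nrow(t$nodes) == 0L) {
    abort("cannot align an empty glycan", class = "glyqgram_argument")
  }
  ns <- glycan_node_tables(s)
  nt <- glycan_node_tables(t)
  W <- node_score_matrix(ns, nt, node_score, mono_table, bond_table,
                         layer_formula)
  n1 <- length(ns$ids)
  n2 <- length(nt$ids)
  Q <- matrix(0, n1, n2)
  local <- mode == "local"
  # children lists as positional indices, post-order iteration
  for (u in rev(ns$pre)) {
    for (v in rev(nt$pre)) {
      cu <- ns$kids[[u]]
      cv <- nt$kids[[v]]
      best <- W[u, v] + best_assignment(Q, cu, cv)
      if (length(cu)) best <- max(best, max(Q[cu, v]) - gap_penalty)
      if (length(cv)) best <- max(best, max(Q[u, cv]) - gap_penalty)
      if (local) best <- max(best, 0)
      Q[u, v] <- best
    }
  }
  if (local) {
    raw <- max(Q)
    start <- which(Q == raw, arr.ind = TRUE)[1, ]
  } else {
    raw <- Q[ns$root, nt$root]
    start <- c(ns$root, nt$root)
  }
  pairs <- traceback_pairs(Q, W, ns, nt, start[1], start[2], gap_penalty, local)
  list(raw = raw,
       pairs = tibble(node_s = ns$ids[pairs[, 1]], node_t = nt$ids[pairs[, 2]]))
}

glycan_node_tables <- function(g) {
  ids <- g$nodes$node
  pos <- stats::setNames(seq_along(ids), ids)
  kids_ids <- glycan_children(g)
  kids <- map(as.character(ids), function(k) unname(pos[as.character(kids_ids[[k]])]))
  lay <- glycan_layers(g) + (attr(g, "layer_offset") %||% 0L)
  list(ids = ids,
       mono = g$nodes$mono,
       bond = unname(glycan_parent_bonds(g)[as.character(ids)]),
       layer = unname(lay[as.character(ids)]),
       kids = kids,
       root = unname(pos[as.character(g$root)]),
       pre = unname(pos[as.character(preorder_nodes(g))]))
}

node_score_matrix <- function(ns, nt, node_score, mono_table, bond_table,
                              layer_formula) {
  n1 <- length(ns$ids)
  n2 <- length(nt$ids)
  if (node_score == "exact") {
    mono_eq <- outer(ns$mono, nt$mono, "==")
    bond_eq <- outer(ns$bond, nt$bond, "==") |
      outer(ns$bond == WILDCARD_BOND, rep(TRUE, n2), "&") |
      outer(rep(TRUE, n1), nt$bond == WILDCARD_BOND, "&")
    return((mono_eq & bond_eq) * 1)
  }
  sm <- outer(seq_len(n1), seq_len(n2), function(i, j) {
    mono_similarity(ns$mono[i], nt$mono[j], table = mono_table)
  })
  sb <- outer(seq_len(n1), seq_len(n2), function(i, j) {
    bond_similarity(ns$bond[i], nt$bond[j], table = bond_table)
  })
  sl <- outer(ns$layer, nt$layer, function(a, b) layer_similarity(a, b, formula = layer_formula))
  sm * sb * sl
}

# exact best injective assignment of children cu -> cv maximizing sum of Q
best_assignment <- function(Q, cu, cv) {
  if (!length(cu) || !length(cv)) return(0)
  rec <- function(us, vs) {
    if (!length(us) || !length(vs)) return(0)
    best <- rec(us[-1], vs) # leave us[1] unmatched
    for (k in seq_along(vs)) {
      best <- max(best, Q[us[1], vs[k]] + rec(us[-1], vs[-k]))
    }
    best
  }
  rec(cu, cv)
}

assignment_pairs <- function(Q, cu, cv) {
  if (!length(cu) || !length(cv)) return(NULL)
  rec <- function(us, vs) {
    if (!length(us) || !length(vs)) return(list(score = 0, pairs = NULL))
    best <- rec(us[-1], vs)
    for (k in seq_along(vs)) {
      sub <- rec(us[-1], vs[-k])
      cand <- Q[us[1], vs[k]] + sub$score
      if (cand > best$score) {
        best <- list(score = cand,
                     pairs = rbind(c(us[1], vs[k]), sub$pairs))
      }
    }
    best
  }
  rec(cu, cv)$pairs
}

traceback_pairs <- function(Q, W, ns, nt, u, v, gap, local) {
  out <- matrix(integer(), 0, 2)
  walk <- function(u, v) {
    val <- Q[u, v]
    if (local && val <= 0) return()
    cu <- ns$kids[[u]]
    cv <- nt$kids[[v]]
    if (length(cu) && any(abs(Q[cu, v] - gap - val) < 1e-12)) {
      walk(cu[which(abs(Q[cu, v] - gap - val) < 1e-12)[1]], v)
      return()
    }
    if (length(cv) && any(abs(Q[u, cv] - gap - val) < 1e-12)) {
      walk(u, cv[which(abs(Q[u, cv] - gap - val) < 1e-12)[1]])
      return()
    }
    if (W[u, v] > 0) out <<- rbind(out, c(u, v))
    ap <- assignment_pairs(Q, cu, cv)
    for (p in seq_len(nrow(ap %||% matrix(integer(), 0, 2)))) {
      walk(ap[p, 1], ap[p, 2])
    }
  }
  walk(u, v)
  out
}

#' Normalized KCaM similarity score
#'
#' Scales the raw alignment score into the 0-100 range by geometric-mean
#' self-score normalization: `100 * raw(s,t) / sqrt(raw(s,s) * raw(t,t))`,
#' clamped to `[0, 100]`.  Any glycan scores 100 against itself, and the
#' score is symmetric.
#'
#' @inheritParams kcam_align
#' @return A number in `[0, 100]`.
#' @export
kcam_score <- function(s, t, mode = c("global", "local"),
                       node_score = c("exact", "linkage"),
                       gap_penalty = 0,
                       mono_table = NULL,
                       bond_table = bond_similarity_table(),
                       layer_formula = function(d) 1 / (1 + d)) {
  args <- list(mode = match.arg(mode), node_score = match.arg(node_score),
               gap_penalty = gap_penalty, mono_table = mono_table,
               bond_table = bond_table, layer_formula = layer_formula)
  raw_st <- do.call(kcam_align, c(list(s, t), args))$raw
  raw_ss <- do.call(kcam_align, c(list(s, s), args))$raw
  raw_tt <- do.call(kcam_align, c(list(t, t), args))$raw
  normalize_alignment(raw_st, raw_ss, raw_tt)
}

normalize_alignment <- function(raw_st, raw_ss, raw_tt) {
  if (raw_ss <= 0 || raw_tt <= 0) {
    abort("self-alignment score is zero; node scoring has a zero diagonal",
          class = "glyqgram_scoring")
  }
  min(max(100 * raw_st / sqrt(raw_ss * raw_tt), 0), 100)
}

#' Materialize a q-gram as a small glycan
#'
#' The apex becomes the root (carrying the wildcard parent bond), the first
#' canonical chain descends from it, and for bent q-grams the second chain
#' descends from the apex as a second branch.  The q-gram's representative
#' layer is recorded as a `layer_offset` attribute so that
#' linkage-weighted alignment sees the true layers of the original
#' context.
#'
#' @param entry A q-gram (one row of a [qgram_index()], or a list with
#'   fields `q`, `s1`, `s2`, `layer`, `monos`, `bonds`).
#' @return A `glycan` with `q` nodes.
#' @export
qgram_as_glycan <- function(entry) {
  e <- as_qgram_fields(entry)
  q <- e$q
  nodes <- tibble(node = seq_len(q), mono = e$monos)
  if (q > 1L) {
    # nodes 2..s1 form the first chain under the apex; nodes s1+1..q the second
    first <- if (e$s1 > 1L) 2:e$s1 else integer()
    second <- if (e$s2 > 0L) (e$s1 + 1L):q else integer()
    parent <- integer(q - 1L)
    if (length(first)) parent[first - 1L] <- c(1L, head(first, -1L))
    if (length(second)) parent[second - 1L] <- c(1L, head(second, -1L))
    edges <- tibble(child = 2:q, parent = parent, bond = e$bonds)
  } else {
    edges <- NULL
  }
  g <- glycan(nodes, edges, id = e$key %||% "qgram")
  attr(g, "layer_offset") <- e$layer %||% 0L
  g
}

#' @rdname qgram_similarity
#' @export
lk_matrix <- function(index, ...) qgram_similarity(index, method = "lk", ...)

#' @rdname qgram_similarity
#' @export
km_matrix <- function(index, ...) qgram_similarity(index, method = "km", ...)

#' @rdname qgram_similarity
#' @param ... Passed on to [qgram_similarity()].
#' @export
lkm_matrix <- function(index, ...) qgram_similarity(index, method = "lkm", ...)
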