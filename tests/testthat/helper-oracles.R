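# Independent brute-force oracles. These deliberately share no code with the
# package internals beyond the public glycan accessors, so that agreement is
# evidence of correctness rather than of shared bugs.

# --- q-gram oracle: enumerate every q-node subset, keep those whose induced
# subgraph is connected with every node of degree <= 2 inside the subset,
# and canonicalize from first principles.
oracle_qgrams <- function(g, q) {
  tib <- tibble::as_tibble(g)
  nodes <- tib$node
  parent <- stats::setNames(tib$parent, tib$node)
  mono <- stats::setNames(tib$mono, tib$node)
  bond <- stats::setNames(tib$bond, tib$node)
  layer <- stats::setNames(tib$layer, tib$node)
  if (q > length(nodes)) return(character())
  subs <- utils::combn(nodes, q, simplify = FALSE)
  keys <- character()
  for (sel in subs) {
    ssel <- as.character(sel)
    # induced edges: node -> parent when both in the subset
    deg <- stats::setNames(rep(0L, q), sel)
    n_edges <- 0L
    ok <- TRUE
    for (u in ssel) {
      p <- parent[[u]]
      if (!is.na(p) && p %in% sel) {
        n_edges <- n_edges + 1L
        deg[[u]] <- deg[[u]] + 1L
        deg[[as.character(p)]] <- deg[[as.character(p)]] + 1L
      }
    }
    if (n_edges != q - 1L) next           # not connected (tree subsets)
    if (any(deg > 2L)) next               # not a path
    # apex: the unique subset node whose parent is outside the subset
    apex <- sel[vapply(ssel, function(u) {
      p <- parent[[u]]
      is.na(p) || !(p %in% sel)
    }, logical(1))]
    if (length(apex) != 1L) next          # disconnected would hit this too
    # walk the (up to two) chains below the apex
    kids_in <- function(u) sel[!is.na(parent[as.character(sel)]) &
                                 parent[as.character(sel)] == u]
    chain_from <- function(u) {
      out <- u
      repeat {
        k <- kids_in(out[length(out)])
        if (length(k) == 0L) break
        stopifnot(length(k) == 1L)
        out <- c(out, k)
      }
      out
    }
    tops <- kids_in(apex)
    chains <- lapply(tops, chain_from)
    lens <- vapply(chains, length, integer(1))
    seqs_m <- vapply(chains, function(ch) paste(mono[as.character(ch)], collapse = ";"),
                     character(1))
    seqs_b <- vapply(chains, function(ch) paste(bond[as.character(ch)], collapse = ";"),
                     character(1))
    ord <- order(-lens, seqs_m, seqs_b, method = "radix")
    chains <- chains[ord]
    first <- if (length(chains) >= 1L) chains[[1]] else integer()
    second <- if (length(chains) >= 2L) chains[[2]] else integer()
    monos <- c(mono[[as.character(apex)]], mono[as.character(first)],
               mono[as.character(second)])
    bonds <- c(bond[as.character(first)], bond[as.character(second)])
    keys <- c(keys, paste0(q, "|", 1L + length(first), ",", length(second), "|",
                           paste(monos, collapse = ";"), "|",
                           paste(bonds, collapse = ";")))
  }
  keys
}

# --- alignment oracle: score every injective partial mapping that preserves
# the ancestor partial order in both directions (incomparable nodes map to
# incomparable nodes).  Maximum total node score over all such mappings;
# valid for gap penalty 0 and non-negative scores.
oracle_align <- function(s, t, w) {
  ts_ <- tibble::as_tibble(s)
  tt_ <- tibble::as_tibble(t)
  anc <- function(tb) {
    parent <- stats::setNames(tb$parent, tb$node)
    out <- list()
    for (u in tb$node) {
      a <- integer()
      p <- parent[[as.character(u)]]
      while (!is.na(p)) {
        a <- c(a, p)
        p <- parent[[as.character(p)]]
      }
      out[[as.character(u)]] <- a
    }
    out
  }
  anc_s <- anc(ts_)
  anc_t <- anc(tt_)
  rel <- function(a, anc_map, u, v) {
    # 1: u ancestor of v, -1: v ancestor of u, 0: equal, 2: incomparable
    if (u == v) return(0L)
    if (u %in% anc_map[[as.character(v)]]) return(1L)
    if (v %in% anc_map[[as.character(u)]]) return(-1L)
    2L
  }
  ns <- ts_$node
  nt <- tt_$node
  best <- 0
  k_max <- min(length(ns), length(nt))
  for (k in seq_len(k_max)) {
    su <- utils::combn(ns, k, simplify = FALSE)
    sv <- utils::combn(nt, k, simplify = FALSE)
    perms <- all_perms(k)
    for (U in su) for (V in sv) for (p in perms) {
      Vp <- V[p]
      score <- 0
      valid <- TRUE
      for (i in seq_len(k)) {
        score <- score + w[as.character(U[i]), as.character(Vp[i])]
        if (i > 1L) for (j in seq_len(i - 1L)) {
          if (rel(NULL, anc_s, U[i], U[j]) != rel(NULL, anc_t, Vp[i], Vp[j])) {
            valid <- FALSE
            break
          }
        }
        if (!valid) break
      }
      if (valid && score > best) best <- score
    }
  }
  best
}

all_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# exact node-score matrix for the oracle, matching the "exact" scoring rule
oracle_exact_w <- function(s, t) {
  ts_ <- tibble::as_tibble(s)
  tt_ <- tibble::as_tibble(t)
  bs <- ifelse(is.na(ts_$bond), "*", ts_$bond)
  bt <- ifelse(is.na(tt_$bond), "*", tt_$bond)
  w <- outer(seq_len(nrow(ts_)), seq_len(nrow(tt_)), function(i, j) {
    (ts_$mono[i] == tt_$mono[j]) &
      (bs[i] == bt[j] | bs[i] == "*" | bt[j] == "*")
  }) * 1
  dimnames(w) <- list(ts_$node, tt_$node)
  w
}

# --- subtree containment oracle: does `g` contain `frag` as a rooted
# labeled subtree (frag root mapped to any node of g, children mapped
# injectively, monos and internal bonds equal)?
oracle_contains <- function(g, frag) {
  gm <- stats::setNames(g$nodes$mono, g$nodes$node)
  fm <- stats::setNames(frag$nodes$mono, frag$nodes$node)
  g_kids <- split(g$edges$child, factor(g$edges$parent, levels = g$nodes$node))
  f_kids <- split(frag$edges$child, factor(frag$edges$parent, levels = frag$nodes$node))
  g_bond <- stats::setNames(g$edges$bond, g$edges$child)
  f_bond <- stats::setNames(frag$edges$bond, frag$edges$child)
  match_at <- function(fu, gu) {
    if (fm[[as.character(fu)]] != gm[[as.character(gu)]]) return(FALSE)
    fks <- f_kids[[as.character(fu)]]
    if (length(fks) == 0L) return(TRUE)
    gks <- g_kids[[as.character(gu)]]
    if (length(gks) < length(fks)) return(FALSE)
    # try all injective child assignments
    try_assign <- function(fks, gks) {
      if (length(fks) == 0L) return(TRUE)
      for (i in seq_along(gks)) {
        if (f_bond[[as.character(fks[1])]] == g_bond[[as.character(gks[i])]] &&
            match_at(fks[1], gks[i]) &&
            try_assign(fks[-1], gks[-i])) {
          return(TRUE)
        }
      }
      FALSE
    }
    try_assign(fks, gks)
  }
  any(vapply(g$nodes$node, function(u) match_at(frag$root, u), logical(1)))
}
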