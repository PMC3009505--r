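#' Enumerate the q-grams of a glycan
#'
#' A q-gram is a connected subtree with `q` nodes in which every node has at
#' most two neighbors inside the subtree — i.e. a subtree isomorphic to a
#' path.  In a rooted tree such a path is either a straight
#' ancestor-to-descendant chain, or a *bent* path whose topmost node (the
#' apex) carries two descending chains.  Each occurrence is canonicalized
#' to a tuple of
#'
#' * its shape `(s1, s2)`: the node counts of the first chain (apex
#'   included) and second chain, `s1 + s2 = q`, `s1 >= s2 >= 0` (`s2 = 0`
#'   for straight chains);
#' * the ordered monosaccharide labels, apex first, walking the first chain
#'   top-down then the second chain top-down;
#' * the ordered bond labels along the same walk (each node's bond towards
#'   its parent; `q - 1` of them);
#' * the layer of the apex (its linkage distance from the glycan root).
#'
#' For bent paths the two descending chains below the apex are ordered
#' canonically — longer chain first, ties broken by the lexicographic
#' monosaccharide then bond label sequences — so that identically labeled
#' embeddings always canonicalize to the same key.  The canonical key
#' encodes `(q, shape, monos, bonds)`; the layer is deliberately excluded,
#' so identical substructures at different depths count as the same
#' feature, and layers enter only similarity computations.
#'
#' @param g A `glycan`.
#' @param q Number of nodes per q-gram, at least 1.
#' @param straight_only If `TRUE`, enumerate only straight
#'   ancestor-to-descendant chains (no bent paths).
#' @return A tibble with one row per occurrence: `key`, `q`, `s1`, `s2`,
#'   `layer`, `monos` (list of character), `bonds` (list of character).
#' @export
enumerate_qgrams <- function(g, q, straight_only = FALSE) {
  if (!is.numeric(q) || length(q) != 1L || q < 1 || q != round(q)) {
    abort("q must be a single integer >= 1", class = "glyqgram_argument")
  }
  q <- as.integer(q)
  kids <- glycan_children(g)
  mono <- glycan_monos(g)
  pbond <- glycan_parent_bonds(g)
  lay <- glycan_layers(g)

  # all downward chains of `len` nodes starting at u
  chains <- function(u, len) {
    if (len == 1L) return(list(u))
    out <- list()
    for (v in kids[[as.character(u)]]) {
      for (tail in chains(v, len - 1L)) {
        out[[length(out) + 1L]] <- c(u, tail)
      }
    }
    out
  }

  occ <- list()
  for (u in g$nodes$node) {
    for (ch in chains(u, q)) { # straight: apex is the top node
      occ[[length(occ) + 1L]] <- canon_occurrence(
        q, u, ch[-1], integer(), mono, pbond, lay)
    }
    if (!straight_only && q >= 3L) {
      ks <- kids[[as.character(u)]]
      if (length(ks) >= 2L) {
        pairs <- utils::combn(seq_along(ks), 2L)
        for (p in seq_len(ncol(pairs))) {
          c1 <- ks[pairs[1, p]]
          c2 <- ks[pairs[2, p]]
          for (a in 1:(q - 2L)) {
            b <- q - 1L - a
            for (chA in chains(c1, a)) {
              for (chB in chains(c2, b)) {
                occ[[length(occ) + 1L]] <- canon_occurrence(
                  q, u, chA, chB, mono, pbond, lay)
              }
            }
          }
        }
      }
    }
  }
  qgram_tibble(occ, q)
}

# canonicalize one embedding: apex node id plus the node-id vectors of the
# (up to two) descending chains below it; mono/pbond/lay are per-node
# lookup tables keyed by node id
canon_occurrence <- function(q, apex, chainA, chainB, mono, pbond, lay) {
  ka <- as.character(chainA)
  kb <- as.character(chainB)
  if (length(chainB)) {
    a <- list(m = unname(mono[ka]), b = unname(pbond[ka]))
    b <- list(m = unname(mono[kb]), b = unname(pbond[kb]))
    if (chain_lt(b, a)) { tmp <- a; a <- b; b <- tmp }
    first <- a; second <- b
  } else {
    first <- list(m = unname(mono[ka]), b = unname(pbond[ka]))
    second <- list(m = character(), b = character())
  }
  monos <- c(unname(mono[as.character(apex)]), first$m, second$m)
  bonds <- c(first$b, second$b)
  s1 <- 1L + length(first$m)
  s2 <- length(second$m)
  list(key = paste0(q, "|", s1, ",", s2, "|",
                    paste(monos, collapse = ";"), "|",
                    paste(bonds, collapse = ";")),
       q = q, s1 = s1, s2 = s2,
       layer = unname(lay[as.character(apex)]),
       monos = monos, bonds = bonds)
}

# canonical chain order: longer first, then lexicographic mono sequence,
# then lexicographic bond sequence; TRUE if chain b sorts before chain a.
# String comparison is byte-wise (C locale) for locale independence.
chain_lt <- function(b, a) {
  if (length(b$m) != length(a$m)) return(length(b$m) > length(a$m))
  sb <- paste(b$m, collapse = ";")
  sa <- paste(a$m, collapse = ";")
  if (sb != sa) return(c_lt(sb, sa))
  c_lt(paste(b$b, collapse = ";"), paste(a$b, collapse = ";"))
}

c_lt <- function(a, b) {
  if (a == b) return(FALSE)
  order(c(a, b), method = "radix")[1] == 1L
}

qgram_tibble <- function(occ, q) {
  if (!length(occ)) {
    return(tibble(key = character(), q = integer(), s1 = integer(),
                  s2 = integer(), layer = integer(), monos = list(),
                  bonds = list()))
  }
  tibble(key = map_chr(occ, "key"),
         q = q,
         s1 = map_int(occ, "s1"),
         s2 = map_int(occ, "s2"),
         layer = map_int(occ, "layer"),
         monos = map(occ, "monos"),
         bonds = map(occ, "bonds"))
}

#' Build a q-gram index over a glycan collection
#'
#' Collects the union of canonical q-gram keys across the glycans, in
#' first-seen order.  Each entry records a representative layer: since the
#' same labeled substructure can occur at several depths, the entry's layer
#' is the most frequent layer of that key across the corpus (ties broken
#' towards the smaller layer).  The number of entries is the feature-space
#' dimension `d_q`.
#'
#' @param glycans A list of glycans (possibly empty).
#' @inheritParams enumerate_qgrams
#' @return A `qgram_index`: a tibble with columns `key`, `q`, `s1`, `s2`,
#'   `layer`, `monos`, `bonds`, plus attributes `q` and `d_q`.
#' @export
qgram_index <- function(glycans, q, straight_only = FALSE) {
  occ <- bind_rows(map(glycans, enumerate_qgrams, q = q,
                       straight_only = straight_only))
  if (nrow(occ) == 0L) {
    idx <- occ
  } else {
    rep_layer <- occ |>
      count(.data$key, .data$layer, name = "n_occ") |>
      group_by(.data$key) |>
      arrange(dplyr::desc(.data$n_occ), .data$layer, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      ungroup() |>
      select("key", rep_layer = "layer")
    idx <- occ[!duplicated(occ$key), ]
    idx <- left_join(idx, rep_layer, by = "key")
    idx$layer <- idx$rep_layer
    idx$rep_layer <- NULL
  }
  structure(idx, class = c("qgram_index", class(idx)),
            q = as.integer(q), d_q = nrow(idx),
            straight_only = straight_only)
}

#' @export
print.qgram_index <- function(x, ...) {
  cat("<qgram_index> q = ", attr(x, "q"), ", d_q = ", attr(x, "d_q"),
      " distinct q-grams\n", sep = "")
  NextMethod()
}

#' Count-matrix of q-gram occurrences
#'
#' Builds the `d_q x n` matrix whose entry `(i, s)` is the number of
#' embeddings of the i-th indexed q-gram in glycan `s`; column `s` is the
#' q-gram feature vector of that glycan, and the plain q-gram kernel is the
#' Gram matrix of these columns.
#'
#' @param glycans A list of glycans.
#' @param index A [qgram_index()].
#' @param policy What to do when a glycan contains a q-gram absent from the
#'   index: `"strict"` (default) raises an error naming the key —
#'   protecting against silent feature-space leakage between training and
#'   test corpora — while `"extend"` appends new rows to the matrix.
#' @return An integer matrix with q-gram keys as rownames and glycan ids as
#'   colnames.
#' @export
qgram_counts <- function(glycans, index, policy = c("strict", "extend")) {
  policy <- match.arg(policy)
  q <- attr(index, "q")
  so <- attr(index, "straight_only") %||% FALSE
  keys <- index$key
  per_glycan <- map(glycans, function(g) {
    occ <- enumerate_qgrams(g, q, straight_only = so)
    table(occ$key)
  })
  unseen <- setdiff(unique(unlist(map(per_glycan, names))), keys)
  if (length(unseen)) {
    if (policy == "strict") {
      abort(paste0("q-gram not in index: ", unseen[1]),
            class = "glyqgram_unseen_key")
    }
    keys <- c(keys, unseen)
  }
  X <- matrix(0L, nrow = length(keys), ncol = length(glycans),
              dimnames = list(unname(keys), unname(map_chr(glycans, "id"))))
  for (s in seq_along(per_glycan)) {
    tb <- per_glycan[[s]]
    if (length(tb)) X[names(tb), s] <- as.integer(tb)
  }
  X
}
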