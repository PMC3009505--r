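#' Construct a glycan tree
#'
#' A glycan is modeled as a rooted tree whose nodes are monosaccharides (or
#' other residues such as sulfate or the aglycon) and whose edges are
#' glycosidic bonds labeled by anomeric configuration and carbon positions
#' (e.g. `"b1-4"`).  Each node may carry at most four children in addition to
#' its parent; sibling order carries no meaning, so a canonical child order
#' (bond label, child monosaccharide label, child node id) is imposed for
#' deterministic enumeration and serialization.
#'
#' @param nodes A data frame with columns `node` (unique integer ids) and
#'   `mono` (non-empty monosaccharide labels).
#' @param edges A data frame with columns `child`, `parent` (node ids) and
#'   `bond` (non-empty bond labels).  May have zero rows for a single-node
#'   glycan.
#' @param id Identifier of the glycan (used as column name in count and
#'   kernel matrices).
#' @param strict How to treat a node with more than four children:
#'   `"warn"` (default) or `"error"`, or `"ignore"`.
#' @return An object of class `glycan` with elements `id`, `nodes` (tibble),
#'   `edges` (tibble, canonically ordered) and `root` (root node id).
#' @examples
#' g <- glycan(
#'   nodes = data.frame(node = 1:3, mono = c("GlcNAc", "Gal", "Neu5Ac")),
#'   edges = data.frame(child = 2:3, parent = 1:2, bond = c("b1-4", "a2-6"))
#' )
#' glycan_layers(g)
#' @export
glycan <- function(nodes, edges = NULL, id = "g1", strict = c("warn", "error", "ignore")) {
  strict <- match.arg(strict)
  nodes <- tibble::as_tibble(nodes[, c("node", "mono")])
  nodes$node <- as.integer(nodes$node)
  nodes$mono <- as.character(nodes$mono)
  if (nrow(nodes) == 0L) abort("a glycan needs at least one node", class = "glyqgram_empty")
  if (anyDuplicated(nodes$node)) abort("duplicate node ids", class = "glyqgram_invalid")
  if (any(!nzchar(nodes$mono))) abort("empty monosaccharide label", class = "glyqgram_invalid")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(child = integer(), parent = integer(), bond = character())
  } else {
    edges <- tibble::as_tibble(edges[, c("child", "parent", "bond")])
    edges$child <- as.integer(edges$child)
    edges$parent <- as.integer(edges$parent)
    edges$bond <- as.character(edges$bond)
  }
  g <- structure(list(id = as.character(id), nodes = nodes, edges = edges,
                      root = NA_integer_),
                 class = "glycan")
  validate_glycan(g, strict = strict)
}

#' Validate a glycan tree
#'
#' Checks the tree invariants: every edge endpoint is a declared node,
#' exactly one node has no parent (the root), every other node has exactly
#' one parent, the edge relation is acyclic and connected.  A node with more
#' than four children violates the biochemical branching limit of
#' monosaccharides; this raises a warning (or error under `strict =
#' "error"`) but does not invalidate the tree.  Edges are re-sorted into the
#' canonical child order.
#'
#' @param g A `glycan`.
#' @inheritParams glycan
#' @return The validated glycan, with `root` filled in and edges ordered.
#' @export
validate_glycan <- function(g, strict = c("warn", "error", "ignore")) {
  strict <- match.arg(strict)
  ids <- g$nodes$node
  ed <- g$edges
  bad <- setdiff(c(ed$child, ed$parent), ids)
  if (length(bad)) {
    abort(paste0("edge references unknown node id: ", bad[1]),
          class = "glyqgram_parse_edge")
  }
  if (any(!nzchar(ed$bond))) abort("empty bond label", class = "glyqgram_invalid")
  n_par <- table(factor(ed$child, levels = ids))
  if (any(n_par > 1L)) {
    abort(paste0("node ", ids[which(n_par > 1L)[1]], " has multiple parents"),
          class = "glyqgram_invalid")
  }
  roots <- ids[n_par == 0L]
  if (length(roots) == 0L) abort("no root: every node has a parent (cycle)",
                                 class = "glyqgram_cycle")
  if (length(roots) > 1L) {
    abort(paste0("multiple roots: nodes ", paste(roots, collapse = ", "),
                 " have no parent"), class = "glyqgram_multiroot")
  }
  if (nrow(ed) != length(ids) - 1L) {
    abort("edge count must be node count - 1", class = "glyqgram_invalid")
  }
  # reachability from the root proves connectivity (and hence acyclicity,
  # given the edge count and the unique-parent check above)
  kids <- split(ed$child, factor(ed$parent, levels = ids))
  seen <- roots
  frontier <- roots
  while (length(frontier)) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    frontier <- nxt
    seen <- c(seen, nxt)
  }
  if (length(seen) != length(ids)) {
    abort(paste0("disconnected component containing node ",
                 setdiff(ids, seen)[1]), class = "glyqgram_cycle")
  }
  deg <- table(ed$parent)
  if (any(deg > 4L)) {
    msg <- paste0("node ", names(deg)[which(deg > 4L)[1]],
                  " has more than 4 children")
    if (strict == "error") abort(msg, class = "glyqgram_degree")
    if (strict == "warn") warn(msg, class = "glyqgram_degree")
  }
  # canonical child order: (bond code, child mono code, child node id)
  if (nrow(ed)) {
    mono_of <- stats::setNames(g$nodes$mono, g$nodes$node)
    ord <- order(ed$parent, ed$bond, mono_of[as.character(ed$child)], ed$child)
    g$edges <- ed[ord, ]
  }
  g$root <- roots
  g
}

#' Layers of a glycan's nodes
#'
#' The layer of a monosaccharide is the number of glycosidic linkages
#' between it and the root of the glycan: the root is at layer 0 and each
#' child is one layer below its parent.
#'
#' @param g A `glycan`.
#' @return A named integer vector mapping node id to layer.
#' @export
glycan_layers <- function(g) {
  ids <- g$nodes$node
  layer <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  layer[as.character(g$root)] <- 0L
  frontier <- g$root
  while (length(frontier)) {
    rows <- g$edges$parent %in% frontier
    ch <- g$edges$child[rows]
    layer[as.character(ch)] <- layer[as.character(g$edges$parent[rows])] + 1L
    frontier <- ch
  }
  layer
}

# children of each node in canonical order, as a list indexed by node id
glycan_children <- function(g) {
  kids <- split(g$edges$child, factor(g$edges$parent, levels = g$nodes$node))
  names(kids) <- as.character(g$nodes$node)
  kids
}

# parent bond of each node; the root carries the wildcard bond
glycan_parent_bonds <- function(g) {
  pb <- stats::setNames(rep(WILDCARD_BOND, nrow(g$nodes)), g$nodes$node)
  pb[as.character(g$edges$child)] <- g$edges$bond
  pb
}

glycan_monos <- function(g) stats::setNames(g$nodes$mono, g$nodes$node)

#' @export
print.glycan <- function(x, ...) {
  cat("<glycan> ", x$id, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges, root = ", x$root, "\n", sep = "")
  lay <- glycan_layers(x)
  mono <- glycan_monos(x)
  pb <- glycan_parent_bonds(x)
  ord <- preorder_nodes(x)
  for (u in ord) {
    k <- as.character(u)
    indent <- strrep("  ", lay[k])
    b <- if (pb[k] == WILDCARD_BOND) "" else paste0(" -", pb[k], "-")
    cat(indent, mono[k], b, "\n", sep = "")
  }
  invisible(x)
}

# depth-first pre-order of node ids following the canonical child order
preorder_nodes <- function(g) {
  kids <- glycan_children(g)
  out <- integer(nrow(g$nodes))
  i <- 0L
  stack <- g$root
  while (length(stack)) {
    u <- stack[1]
    stack <- stack[-1]
    i <- i + 1L
    out[i] <- u
    stack <- c(kids[[as.character(u)]], stack)
  }
  out
}

#' @method as_tibble glycan
#' @export
as_tibble.glycan <- function(x, ...) {
  lay <- glycan_layers(x)
  pb <- glycan_parent_bonds(x)
  par <- stats::setNames(rep(NA_integer_, nrow(x$nodes)), x$nodes$node)
  par[as.character(x$edges$child)] <- x$edges$parent
  tibble(id = x$id, node = x$nodes$node, mono = x$nodes$mono,
         parent = unname(par[as.character(x$nodes$node)]),
         bond = ifelse(x$nodes$node == x$root, NA_character_,
                       unname(pb[as.character(x$nodes$node)])),
         layer = unname(lay[as.character(x$nodes$node)]))
}
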