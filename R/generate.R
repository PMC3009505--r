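#' Configuration for the random glycan generator
#'
#' Trees are grown top-down from the root: each of `max_children` child
#' slots of a node is filled independently with probability `branch_prob`,
#' growth stops at `max_depth`, and whole trees are rejection-sampled until
#' the node count falls in `[min_nodes, max_nodes]` (at most 10,000
#' attempts).  Node and bond labels are drawn from the supplied frequency
#' tables, which default to the observed residue and linkage frequencies of
#' the KEGG glycan database ([glycan_mono_freqs()], [glycan_bond_freqs()]).
#'
#' The defaults emulate mammalian-style glycans of modest size (5-15
#' residues, branching limited to four children as chemistry allows).
#'
#' @param mono_freqs,bond_freqs Data frames with columns `label`, `freq`
#'   (renormalized to sum 1).
#' @param min_nodes,max_nodes Node-count range of accepted trees.
#' @param max_depth Maximum layer of any node.
#' @param max_children Maximum children per node, at most 4.
#' @param branch_prob Probability each child slot is occupied.
#' @return A `generator_config` list.
#' @export
generator_config <- function(mono_freqs = glycan_mono_freqs(),
                             bond_freqs = glycan_bond_freqs(),
                             min_nodes = 5L, max_nodes = 15L,
                             max_depth = 6L, max_children = 4L,
                             branch_prob = 0.3) {
  stopifnot(min_nodes >= 1L, max_nodes >= min_nodes,
            max_children >= 1L, max_children <= 4L,
            branch_prob >= 0, branch_prob <= 1, max_depth >= 0L)
  norm <- function(d) {
    d <- tibble::as_tibble(d[, c("label", "freq")])
    if (any(d$freq < 0) || sum(d$freq) <= 0) {
      abort("frequencies must be non-negative with positive sum",
            class = "glyqgram_config")
    }
    d$freq <- d$freq / sum(d$freq)
    d
  }
  # feasibility: a full tree of depth max_depth and arity max_children must
  # be able to hold min_nodes
  cap <- sum(max_children^(0:max_depth))
  if (cap < min_nodes) {
    abort("min_nodes unreachable at max_depth with max_children",
          class = "glyqgram_config")
  }
  if (min_nodes > 1L && (branch_prob == 0 || max_depth == 0L)) {
    abort("config cannot grow beyond a single node", class = "glyqgram_config")
  }
  structure(list(mono_freqs = norm(mono_freqs), bond_freqs = norm(bond_freqs),
                 min_nodes = as.integer(min_nodes),
                 max_nodes = as.integer(max_nodes),
                 max_depth = as.integer(max_depth),
                 max_children = as.integer(max_children),
                 branch_prob = branch_prob),
            class = "generator_config")
}

#' Draw a random glycan tree
#'
#' Consumes the current R random-number stream; call `set.seed()` (or use
#' [generate_glycans()] / [planted_dataset()], which seed for you) for
#' reproducibility.
#'
#' @param cfg A [generator_config()].
#' @param id Identifier for the generated glycan.
#' @return A valid `glycan` with node count in `[min_nodes, max_nodes]`.
#' @export
random_glycan <- function(cfg = generator_config(), id = "g1") {
  stopifnot(inherits(cfg, "generator_config"))
  for (attempt in seq_len(10000L)) {
    g <- grow_glycan(cfg, id)
    if (nrow(g$nodes) >= cfg$min_nodes && nrow(g$nodes) <= cfg$max_nodes) {
      return(validate_glycan(g))
    }
  }
  abort("could not draw a tree in the configured node-count range",
        class = "glyqgram_config")
}

grow_glycan <- function(cfg, id) {
  draw_mono <- function(n) sample(cfg$mono_freqs$label, n, replace = TRUE,
                                  prob = cfg$mono_freqs$freq)
  draw_bond <- function(n) sample(cfg$bond_freqs$label, n, replace = TRUE,
                                  prob = cfg$bond_freqs$freq)
  nodes <- list(node = 1L, mono = draw_mono(1L))
  edges <- list(child = integer(), parent = integer(), bond = character())
  frontier <- c("1" = 0L) # node id -> depth
  next_id <- 2L
  while (length(frontier)) {
    u <- as.integer(names(frontier)[1])
    depth <- frontier[[1]]
    frontier <- frontier[-1]
    if (depth >= cfg$max_depth) next
    n_kids <- sum(runif(cfg$max_children) < cfg$branch_prob)
    if (n_kids == 0L) next
    if (length(nodes$node) + n_kids > cfg$max_nodes) {
      n_kids <- max(0L, cfg$max_nodes - length(nodes$node))
      if (n_kids == 0L) break
    }
    ids <- next_id + seq_len(n_kids) - 1L
    next_id <- next_id + n_kids
    nodes$node <- c(nodes$node, ids)
    nodes$mono <- c(nodes$mono, draw_mono(n_kids))
    edges$child <- c(edges$child, ids)
    edges$parent <- c(edges$parent, rep(u, n_kids))
    edges$bond <- c(edges$bond, draw_bond(n_kids))
    frontier <- c(frontier, stats::setNames(rep(depth + 1L, n_kids), ids))
  }
  structure(list(id = id, nodes = tibble::as_tibble(nodes),
                 edges = tibble::as_tibble(edges), root = 1L),
            class = "glycan")
}

#' Generate a seeded list of random glycans
#'
#' @param n Number of glycans.
#' @param cfg A [generator_config()].
#' @param seed Integer seed; `NULL` uses the current stream.
#' @param prefix Id prefix (`prefix1`, `prefix2`, ...).
#' @return A named list of glycans.
#' @export
generate_glycans <- function(n, cfg = generator_config(), seed = NULL,
                             prefix = "g") {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0(prefix, seq_len(n))
  stats::setNames(map(ids, function(i) random_glycan(cfg, id = i)), ids)
}

#' Define a motif fragment to plant into positive glycans
#'
#' A motif is a small glycan fragment (typically 2-4 residues) standing in
#' for a disease-associated substructure.  [planted_dataset()] grafts it
#' into every positive-class glycan at a layer drawn from
#' `graft_layer_range`.
#'
#' @param fragment A valid `glycan` to use as the motif.
#' @param graft_layer_range Inclusive range of layers at which the motif
#'   root may be grafted.
#' @return A `motif_spec`.
#' @examples
#' lacnac <- glycan(
#'   nodes = data.frame(node = 1:2, mono = c("Gal", "GlcNAc")),
#'   edges = data.frame(child = 2, parent = 1, bond = "b1-4")
#' )
#' spec <- motif_spec(lacnac)
#' @export
motif_spec <- function(fragment, graft_layer_range = c(0L, 2L)) {
  stopifnot(inherits(fragment, "glycan"), length(graft_layer_range) == 2L,
            graft_layer_range[1] >= 0L,
            graft_layer_range[2] >= graft_layer_range[1])
  structure(list(fragment = validate_glycan(fragment),
                 graft_layer_range = as.integer(graft_layer_range)),
            class = "motif_spec")
}

#' Generate a planted-motif two-class glycan dataset
#'
#' Negatives are drawn from the background generator unmodified.  Each
#' positive is a background draw into which the motif fragment is grafted:
#' a node at an allowed layer is chosen uniformly and replaced by the motif
#' root; the displaced subtree is reattached below the motif's deepest leaf
#' when its degree permits, and dropped otherwise.  Optionally the motif's
#' bonds are perturbed in a fraction of positives (`swap_frac`), replacing
#' occurrences of `bond_swap[1]` by `bond_swap[2]` inside the planted copy —
#' this emulates a motif whose linkage varies across carriers.
#'
#' @param n_pos,n_neg Class sizes; labels are `+1` / `-1`.
#' @param motif A [motif_spec()].
#' @param cfg Background [generator_config()].
#' @param seed Integer seed.
#' @param bond_swap Length-2 character vector, or `NULL` for no
#'   perturbation.
#' @param swap_frac Fraction of positives whose planted motif is perturbed.
#' @return A list with elements `glycans` (named list) and `labels` (named
#'   vector of `+1`/`-1`, aligned with `glycans`).
#' @export
planted_dataset <- function(n_pos, n_neg, motif, cfg = generator_config(),
                            seed = NULL, bond_swap = NULL, swap_frac = 0.5) {
  stopifnot(inherits(motif, "motif_spec"))
  motif_depth <- max(glycan_layers(motif$fragment))
  if (motif$graft_layer_range[1] + motif_depth > cfg$max_depth) {
    abort("motif deeper than the background max_depth",
          class = "glyqgram_config")
  }
  if (!is.null(seed)) set.seed(seed)
  n_swap <- if (is.null(bond_swap)) 0L else round(swap_frac * n_pos)
  pos <- map(seq_len(n_pos), function(i) {
    frag <- motif$fragment
    if (i <= n_swap) {
      frag$edges$bond[frag$edges$bond == bond_swap[1]] <- bond_swap[2]
    }
    g <- random_glycan(cfg, id = paste0("pos", i))
    graft_motif(g, frag, motif$graft_layer_range, cfg$max_depth)
  })
  neg <- map(seq_len(n_neg), function(i) random_glycan(cfg, id = paste0("neg", i)))
  glycans <- c(pos, neg)
  names(glycans) <- map_chr(glycans, "id")
  labels <- stats::setNames(rep(c(1, -1), c(n_pos, n_neg)), names(glycans))
  list(glycans = glycans, labels = labels)
}

# replace a uniformly chosen node at an allowed layer with the motif root;
# the displaced subtree goes below the motif's deepest leaf if degree allows
graft_motif <- function(g, frag, layer_range, max_depth) {
  lay <- glycan_layers(g)
  frag_depth <- max(glycan_layers(frag))
  ok <- names(lay)[lay >= layer_range[1] & lay <= layer_range[2] &
                     lay + frag_depth <= max_depth]
  if (length(ok) == 0L) ok <- as.character(g$root)
  target <- as.integer(sample(ok, 1L))
  # relabel motif nodes to fresh ids
  off <- max(g$nodes$node)
  f_nodes <- frag$nodes
  f_nodes$node <- f_nodes$node + off
  f_edges <- frag$edges
  if (nrow(f_edges)) {
    f_edges$child <- f_edges$child + off
    f_edges$parent <- f_edges$parent + off
  }
  f_root <- frag$root + off
  f_lay <- glycan_layers(frag)
  deepest <- as.integer(names(f_lay)[which.max(f_lay)]) + off

  # detach the target's subtree
  sub <- subtree_nodes(g, target)
  keep_nodes <- g$nodes[!(g$nodes$node %in% sub), ]
  keep_edges <- g$edges[!(g$edges$child %in% sub), ]
  parent_edge <- g$edges[g$edges$child == target, ]

  nodes <- bind_rows(keep_nodes, f_nodes)
  edges <- bind_rows(keep_edges, f_edges)
  if (nrow(parent_edge)) {
    edges <- bind_rows(edges, tibble(child = f_root,
                                     parent = parent_edge$parent,
                                     bond = parent_edge$bond))
  }
  # reattach the displaced children of the target under the motif's deepest
  # leaf, degree permitting and depth permitting
  disp <- g$edges[g$edges$parent == target, ]
  if (nrow(disp)) {
    slot <- 4L
    depth_left <- max_depth - (unname(glycan_layers(g)[as.character(target)]) + max(f_lay))
    for (k in seq_len(nrow(disp))) {
      d_sub <- subtree_nodes(g, disp$child[k])
      d_depth <- diff(range(glycan_layers(g)[as.character(d_sub)]))
      if (slot > 0L && d_depth < depth_left) {
        nodes <- bind_rows(nodes, g$nodes[g$nodes$node %in% d_sub, ])
        edges <- bind_rows(edges, g$edges[g$edges$child %in% d_sub, ])
        edges$parent[edges$child == disp$child[k]] <- deepest
        slot <- slot - 1L
      }
    }
  }
  out <- glycan(nodes, edges, id = g$id, strict = "ignore")
  validate_glycan(out, strict = "warn")
}

# all node ids in the subtree rooted at u (including u)
subtree_nodes <- function(g, u) {
  out <- u
  frontier <- u
  while (length(frontier)) {
    ch <- g$edges$child[g$edges$parent %in% frontier]
    out <- c(out, ch)
    frontier <- ch
  }
  out
}
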