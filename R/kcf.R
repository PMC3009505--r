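#' Parse a KCF-style glycan record
#'
#' Reads one glycan from the KEGG Chemical Function (KCF) text skeleton:
#' an `ENTRY` line, a `NODE` block listing node index and residue label
#' (2-D coordinate columns are ignored) and an `EDGE` block listing one
#' glycosidic bond per line.  Two edge-line dialects are accepted:
#'
#' * KEGG style `1  2:b1  1:4` — edge index, child node with the anomeric
#'   half of the bond, parent node with the acceptor position; the bond
#'   label is reassembled as `"b1-4"`;
#' * flat style `1  2  1  b1-4` — edge index, child node, parent node,
#'   full bond label (this is the dialect [write_kcf()] emits).
#'
#' Only topology and labels are semantic; everything else in the record is
#' ignored.
#'
#' @param text A character scalar (possibly multi-line) or character vector
#'   of lines holding exactly one record.
#' @inheritParams glycan
#' @return A validated [glycan()].
#' @seealso [read_kcf()] for multi-record files, [write_kcf()].
#' @export
parse_kcf <- function(text, strict = c("warn", "error", "ignore")) {
  strict <- match.arg(strict)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("\r$", "", lines)
  keyw <- function(l) sub("^([A-Z/]+).*$", "\\1", l)
  starts <- grepl("^[A-Z/]", lines)
  id <- "glycan"
  node_lines <- character()
  edge_lines <- character()
  block <- ""
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(trimws(l))) next
    if (starts[i]) {
      block <- keyw(l)
      body <- trimws(sub("^[A-Z/]+", "", l))
      if (block == "ENTRY" && nzchar(body)) id <- strsplit(body, "\\s+")[[1]][1]
      next
    }
    if (block == "NODE") node_lines <- c(node_lines, l)
    if (block == "EDGE") edge_lines <- c(edge_lines, l)
  }
  if (length(node_lines) == 0L) {
    abort("empty NODE block", class = "glyqgram_parse_node")
  }
  nodes <- map(node_lines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 2L) {
      abort(paste0("malformed NODE line: '", trimws(l), "'"),
            class = "glyqgram_parse_node")
    }
    list(node = suppressWarnings(as.integer(tok[1])), mono = tok[2])
  })
  nodes <- tibble(node = map_int(nodes, "node"), mono = map_chr(nodes, "mono"))
  if (anyNA(nodes$node)) {
    abort("non-integer node index in NODE block", class = "glyqgram_parse_node")
  }
  if (anyDuplicated(nodes$node)) {
    abort(paste0("duplicate node id ", nodes$node[duplicated(nodes$node)][1],
                 " in NODE block"), class = "glyqgram_parse_node")
  }
  edges <- map(edge_lines, function(l) parse_kcf_edge(l))
  edges <- tibble(child = map_int(edges, "child"),
                  parent = map_int(edges, "parent"),
                  bond = map_chr(edges, "bond"))
  glycan(nodes, edges, id = id, strict = strict)
}

parse_kcf_edge <- function(l) {
  tok <- strsplit(trimws(l), "\\s+")[[1]]
  if (length(tok) >= 3L &&
      (grepl(":", tok[2], fixed = TRUE) || grepl(":", tok[3], fixed = TRUE))) {
    a <- strsplit(tok[2], ":", fixed = TRUE)[[1]]
    b <- strsplit(tok[3], ":", fixed = TRUE)[[1]]
    bond <- paste0(if (length(a) > 1L) a[2] else "", "-",
                   if (length(b) > 1L) b[2] else "")
    return(list(child = as.integer(a[1]), parent = as.integer(b[1]), bond = bond))
  }
  if (length(tok) >= 4L) {
    return(list(child = suppressWarnings(as.integer(tok[2])),
                parent = suppressWarnings(as.integer(tok[3])), bond = tok[4]))
  }
  abort(paste0("malformed EDGE line: '", trimws(l), "'"),
        class = "glyqgram_parse_edge")
}

#' Serialize a glycan as a KCF-style record
#'
#' Nodes are renumbered in depth-first pre-order from the root following the
#' canonical child order, so the output is deterministic: two calls on the
#' same glycan yield byte-identical text, and `parse_kcf(write_kcf(g))` is
#' label-isomorphic to `g`.
#'
#' @param g A `glycan`.
#' @return A single character string (without trailing `///`).
#' @export
write_kcf <- function(g) {
  ord <- preorder_nodes(g)
  new_id <- stats::setNames(seq_along(ord), ord)
  mono <- glycan_monos(g)
  out <- c(sprintf("ENTRY     %s          Glycan", g$id),
           sprintf("NODE      %d", length(ord)),
           sprintf("          %d  %s  0  0", new_id[as.character(ord)],
                   mono[as.character(ord)]))
  ed <- g$edges
  if (nrow(ed)) {
    # emit edges ordered by the child's pre-order number
    ord_e <- order(new_id[as.character(ed$child)])
    ed <- ed[ord_e, ]
    out <- c(out, sprintf("EDGE      %d", nrow(ed)),
             sprintf("          %d  %d  %d  %s", seq_len(nrow(ed)),
                     new_id[as.character(ed$child)],
                     new_id[as.character(ed$parent)], ed$bond))
  } else {
    out <- c(out, "EDGE      0")
  }
  paste(out, collapse = "\n")
}

#' Read or write multi-record KCF files
#'
#' Records are separated by lines containing `///`, following the KEGG
#' flat-file convention.
#'
#' @param path File path.
#' @inheritParams glycan
#' @return `read_kcf()`: a named list of glycans (names are record ids).
#' @export
read_kcf <- function(path, strict = c("warn", "error", "ignore")) {
  strict <- match.arg(strict)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  recs <- strsplit(txt, "\n///", fixed = TRUE)[[1]]
  recs <- recs[nzchar(gsub("[/[:space:]]", "", recs))]
  gl <- map(recs, parse_kcf, strict = strict)
  stats::setNames(gl, map_chr(gl, "id"))
}

#' @param glycans A list of glycans.
#' @rdname read_kcf
#' @export
write_kcf_file <- function(glycans, path) {
  txt <- paste0(paste(map_chr(glycans, write_kcf), collapse = "\n///\n"), "\n///")
  writeLines(txt, path)
  invisible(path)
}

#' Decompose a glycosidic bond label
#'
#' Bond labels combine an optional anomeric configuration (`a` or `b`), an
#' optional donor carbon position and an optional acceptor position, e.g.
#' `"b1-4"`, `"a2-3"`, `"-6"` (unknown anomer/donor), `"b1-"` (unknown
#' acceptor), `"1-3"` (unknown anomer).  Unparseable labels return all-`NA`
#' fields; comparison logic treats them as opaque codes.
#'
#' @param bond Character vector of bond labels.
#' @return A tibble with columns `bond`, `anomer`, `donor`, `acceptor`.
#' @export
parse_bond <- function(bond) {
  m <- regmatches(bond, regexec("^([ab]?)([0-9]*)-([0-9]*)$", bond))
  tibble(
    bond = bond,
    anomer = map_chr(m, function(x) if (length(x) && nzchar(x[2])) x[2] else NA_character_),
    donor = map_int(m, function(x) if (length(x) && nzchar(x[3])) as.integer(x[3]) else NA_integer_),
    acceptor = map_int(m, function(x) if (length(x) && nzchar(x[4])) as.integer(x[4]) else NA_integer_)
  )
}

#' Read a two-column label file
#'
#' @param path TSV with glycan id and class label in `{+1, -1}` (header
#'   optional; lines starting with `#` ignored).
#' @return A named numeric vector of labels.
#' @export
read_labels <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (!is.numeric(d[[2]])) {
    d <- d[-1, , drop = FALSE] # header row
    d[[2]] <- as.numeric(d[[2]])
  }
  stats::setNames(d[[2]], as.character(d[[1]]))
}
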