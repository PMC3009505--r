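#' Residue and bond frequencies in the KEGG glycan database
#'
#' Occurrence frequencies of the 24 most frequent monosaccharides (and
#' other residues: sulfate `S`, phosphate `P`, ceramide `Cer`, asparagine
#' `Asn`, and the unspecified residue `*`) and the 24 most frequent
#' glycosidic-bond labels, as tallied over the KEGG glycan database.  These
#' are the default label pools of the random-glycan generator; non-sugar
#' residues are treated as ordinary node labels.
#'
#' @return A tibble with columns `label` and `freq` (summing to 1 after
#'   renormalization of the published percentages).
#' @export
glycan_mono_freqs <- function() {
  d <- tibble(
    label = c("GlcNAc", "Gal", "Man", "Glc", "LFuc", "Neu5Ac", "S", "GalNAc",
              "LRha", "Xyl", "GlcA", "GlcN", "*", "Cer", "P", "Lgro-manHep",
              "Asn", "Kdo", "Fruf", "LIdoA", "GalA", "LAraf", "Neu5Gc", "Galf"),
    freq = c(0.1833, 0.1712, 0.1486, 0.1041, 0.042, 0.0375, 0.0371, 0.0364,
             0.0225, 0.0198, 0.0159, 0.015, 0.014, 0.0116, 0.0108, 0.0082,
             0.0076, 0.0069, 0.005, 0.0049, 0.0047, 0.0043, 0.0035, 0.0033)
  )
  d$freq <- d$freq / sum(d$freq)
  d
}

#' @rdname glycan_mono_freqs
#' @export
glycan_bond_freqs <- function() {
  d <- tibble(
    label = c("b1-4", "a1-3", "b1-3", "a1-6", "b1-2", "a1-2", "a1-4", "b1-6",
              "a2-3", "-6", "a2-6", "-2", "b1-", "b1-1", "a1-", "-4", "-3",
              "-", "a1-5", "a2-8", "1-3", "1-", "1-4", "a2-4"),
    freq = c(0.272, 0.1156, 0.0997, 0.0793, 0.0669, 0.0656, 0.0617, 0.0419,
             0.0279, 0.0206, 0.0201, 0.0172, 0.0145, 0.0134, 0.0099, 0.0097,
             0.0091, 0.0053, 0.0052, 0.0037, 0.0037, 0.0036, 0.0036, 0.0025)
  )
  d$freq <- d$freq / sum(d$freq)
  d
}

#' Bond similarity table
#'
#' Loads the glycosidic-bond similarity matrix shipped with the package:
#' similarity in `[0, 1]` between the 15 most frequent bond labels, assigned
#' from the chemical meaning of anomeric configuration and linkage
#' positions (e.g. `b1-4` vs `b1-3` scores 0.9; bonds differing in anomer
#' and position score lower).  The stored lower triangle is symmetrized.
#'
#' Lookups through [bond_similarity()] fall back to 1 for identical labels
#' absent from the table, 1 for the wildcard root bond against anything,
#' and 0 for distinct unlisted pairs.
#'
#' @param path Optional TSV to load instead of the shipped table: first row
#'   and first column give the labels, lower or full triangle accepted.
#' @return A symmetric numeric matrix with bond labels as dimnames.
#' @export
bond_similarity_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "bond_similarity.tsv",
                                package = "glyqgram", mustWork = TRUE)
  read_similarity_tsv(path)
}

read_similarity_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", check.names = FALSE,
                  row.names = 1, stringsAsFactors = FALSE, fill = TRUE)
  m <- as.matrix(d)
  mode(m) <- "numeric"
  m[is.na(m)] <- 0
  labs <- rownames(m)
  if (!identical(labs, colnames(m))) {
    abort("similarity table must have matching row and column labels",
          class = "glyqgram_table")
  }
  m <- pmax(m, t(m)) # symmetrize a lower/upper triangle
  if (any(m < 0 | m > 1)) {
    abort("similarity scores must lie in [0, 1]", class = "glyqgram_table")
  }
  diag(m) <- 1
  m
}

#' Monosaccharide similarity table
#'
#' By default monosaccharide similarity is the identity: 1 for equal
#' labels, 0 otherwise.  A table of graded similarities — for instance
#' scores derived from a chemical-structure comparison such as SIMCOMP —
#' can be supplied as a TSV whose first row and column list the labels.
#' Lookups through [mono_similarity()] return 1 for identical labels even
#' when unlisted, and 0 for distinct unlisted pairs.
#'
#' @param path TSV path, or `NULL` for the identity default.
#' @return A symmetric numeric matrix, or `NULL` meaning identity.
#' @export
mono_similarity_table <- function(path = NULL) {
  if (is.null(path)) return(NULL)
  read_similarity_tsv(path)
}
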