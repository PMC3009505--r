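# Small builders used across tests.

chain_glycan <- function(monos, bonds, id = "chain") {
  n <- length(monos)
  glycan(nodes = data.frame(node = seq_len(n), mono = monos),
         edges = if (n > 1L) {
           data.frame(child = 2:n, parent = 1:(n - 1L), bond = bonds)
         } else NULL,
         id = id)
}

# root with two leaf children
cherry_glycan <- function(monos3, bonds2, id = "cherry") {
  glycan(nodes = data.frame(node = 1:3, mono = monos3),
         edges = data.frame(child = 2:3, parent = c(1, 1), bond = bonds2),
         id = id)
}

lacnac_motif <- function() {
  motif_spec(chain_glycan(c("Gal", "GlcNAc"), "b1-4", id = "lacnac"))
}

small_config <- function(...) {
  generator_config(min_nodes = 3L, max_nodes = 12L, max_depth = 5L,
                   branch_prob = 0.35, ...)
}
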