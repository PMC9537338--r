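# Shared fixtures, all generated in code.

# a small but fully structured simulation config
small_config <- function(...) {
  args <- list(n_cells = 300, n_genes = 800, n_arterial_genes = 30,
               n_venous_genes = 30, n_state_genes_per_state = 60,
               n_tgf_genes = 15, n_bmp_genes = 15, seed = 1)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# deterministic cells x genes matrix with named dims
toy_matrix <- function(n_cells, n_genes, seed = 42, fn = function(n) rnorm(n)) {
  set.seed(seed)
  m <- matrix(fn(n_cells * n_genes), n_cells, n_genes)
  dimnames(m) <- list(sprintf("c%03d", seq_len(n_cells)),
                      sprintf("g%03d", seq_len(n_genes)))
  m
}
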