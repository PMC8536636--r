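# fixtures shared across test files; everything generated in code

# tiny deterministic fold-change matrix
tiny_fc <- function(n_cond = 6L, n_genes = 4L, seed = 42L) {
  set.seed(seed)
  m <- matrix(rnorm(n_cond * n_genes), n_cond, n_genes,
              dimnames = list(sprintf("CPD%02d_24 hr_HI", seq_len(n_cond)),
                              sprintf("g%d", seq_len(n_genes))))
  fold_change_matrix(m)
}

# two planted 10-gene blocks (within-block |cor| ~ 0.9, across ~ 0)
two_block_fc <- function(n_cond = 60L, block = 10L, seed = 7L) {
  set.seed(seed)
  a1 <- rnorm(n_cond); a2 <- rnorm(n_cond)
  vals <- cbind(
    sapply(seq_len(block), function(i) 0.9 * a1 + 0.45 * rnorm(n_cond)),
    sapply(seq_len(block), function(i) 0.9 * a2 + 0.45 * rnorm(n_cond)))
  dimnames(vals) <- list(sprintf("C%03d", seq_len(n_cond)),
                         sprintf("g%02d", seq_len(2 * block)))
  fold_change_matrix(vals)
}

# hand-built frozen module set over a known universe
toy_module_set <- function() {
  module_set(list(
    list(id = 1L, gene_ids = c("g1", "g2", "g3"),
         corEG = c(g1 = 0.95, g2 = 0.8, g3 = -0.6),
         hub_gene = "g1",
         ref_gene_sd = c(g1 = 1.5, g2 = 2, g3 = 1),
         ref_sumz_sd = 2.5, ref_rawscore_sd = 3.1),
    list(id = 2L, gene_ids = c("g4", "g5"),
         corEG = c(g4 = 0.9, g5 = 0.85),
         hub_gene = "g4",
         ref_gene_sd = c(g4 = 0.7, g5 = 1.2),
         ref_sumz_sd = 1.4, ref_rawscore_sd = 1.9)),
    universe = sprintf("g%d", 1:8),
    reference_label = "toy")
}

# small reference fixture + frozen build, computed once per test run
small_build <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- generate_reference(n_genes = 400L, n_modules = 8L,
                                module_size_range = c(8L, 40L),
                                n_conditions = 120L, seed = 11L)
      res <- build_modules(sim$fc, beta = 5, reference_label = "small")
      cache <<- list(sim = sim, build = res)
    }
    cache
  }
})
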