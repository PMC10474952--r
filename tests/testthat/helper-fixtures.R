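# Fixture builders shared across test files. Everything is generated in
# code; no data files.

tiny_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_drugs = 12L, m_cells = 10L, latent_dim = 3L, noise_sd = 0.1,
         zero_row_fraction = 0.2, pair_density = 0.9, n_genes = 15L,
         assoc_sizes = c(target = 15L, disease = 20L, miRNA = 10L, ADR = 15L),
         seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

tiny_bundle <- function(seed = 1L, ...) generate_bundle(tiny_cfg(seed, ...))

# very small model spec for structural and mechanics tests
tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(s = 4L, cnn_channels = c(8L, 8L, 8L), kernel = 3L,
         inner_sizes = c(64L, 32L, 16L, 8L), head_sizes = c(32L, 16L, 8L, 1L),
         lr = 1e-3, batch_size = 64L, max_epochs = 5L),
    list(...))
  do.call(model_spec, args)
}

# random model inputs + pairs for pure model-mechanics tests (no pipeline)
random_inputs <- function(n_drugs, m_cells, Vd = 12L, Vc = 4L, seed = 1L) {
  set.seed(seed)
  list(drug_views = replicate(Vd, matrix(runif(n_drugs * n_drugs),
                                         n_drugs, n_drugs), simplify = FALSE),
       fused = matrix(runif(n_drugs * n_drugs), n_drugs, n_drugs),
       cell_views = replicate(Vc, matrix(rnorm(m_cells * 6), m_cells, 6),
                              simplify = FALSE))
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(unclass(M) - t(unclass(M)))), tol)
}
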