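# Shared fixtures, built in code at test time.

tiny_dataset <- function(seed = 1L, P = 2L, n = 5L, G = 8L) {
  generate_fixture_scrnaseq(fixture_config(
    n_populations = P, cells_per_population = n, n_genes = G,
    markers_per_population = min(2L, G %/% P), seed = seed))
}

# the standard NB recovery fixture: 3 populations x 100 cells, 100 genes
nb_fixture <- function(seed = 1L) {
  generate_fixture_scrnaseq(fixture_config(seed = seed))
}

# small, fast VAE training configuration for tests
test_vae_config <- function(seed = 5L, epochs = 60L) {
  vae_config(latent_dim = 8L, encoder_widths = c(64L, 32L, 16L, 16L),
             decoder_widths = c(16L, 16L, 32L, 64L), epochs = epochs,
             batch_size = 64L, learning_rate = 1e-3, seed = seed)
}

# deterministic uniform assignment over the unit square
uniform_assignment <- function(N = 200L, pops = c("a", "b"), seed = 1L) {
  set.seed(seed)
  spatial_assignment(cell_id = sprintf("c%04d", seq_len(N)),
                     x = runif(N), y = runif(N),
                     population = sample(pops, N, replace = TRUE))
}

expect_tbl_equal <- function(x, y, tol = 1e-12) {
  expect_equal(as.data.frame(x), as.data.frame(y), tolerance = tol)
}
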