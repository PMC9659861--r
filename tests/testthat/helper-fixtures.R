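# Shared fixtures: desk-scale configurations and generated datasets.
# Everything is generated in code under fixed seeds; nothing is stored.

ns <- asNamespace("mcvit")

# micro CAST configuration: smallest legal geometry, for optimisation tests
micro_cast_cfg <- function(...) {
  cast_config_tiny(stage_dims = c(8L, 16L, 16L), stage_heads = c(2L, 2L, 2L),
                   stage_mlp_ratios = c(2, 2, 2), embed_dim_out = 12L, ...)
}

# triplets for a subset of classes at a given scene size
make_patch_set <- function(classes, n_per, seed0, size = 32L,
                           cfg = thw_config(size = size)) {
  triplets <- list()
  labels <- integer(0L)
  s <- seed0
  for (cl in classes) {
    for (i in seq_len(n_per)) {
      s <- s + 1L
      triplets[[length(triplets) + 1L]] <-
        make_triplet(render_scene(cl, s, cfg), cl)
      labels <- c(labels, cl)
    }
  }
  list(triplets = triplets, labels = labels)
}

rand_triplet <- function(size = 32L, seed = 1L) {
  set.seed(seed)
  make_triplet(array(stats::runif(size * size * 3), c(size, size, 3L)), 0L)
}

expect_rel_close <- function(a, b, tol) {
  rel <- max(abs(a - b)) / max(1e-12, max(abs(b)))
  expect_lt(rel, tol)
}
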