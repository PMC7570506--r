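# deterministic in-code fixtures used across test files

random_cube <- function(nr = 6L, nc = 7L, nb = 5L, seed = 1L, mask = FALSE) {
  set.seed(seed)
  cb <- hypercube(array(runif(nr * nc * nb), c(nr, nc, nb)),
                  seq(1000, by = 10, length.out = nb))
  if (mask) cb$mask <- matrix(runif(nr * nc) > 0.4, nr, nc)
  cb
}

# tiny labelled stack + patches for CNN tests: two classes that differ by a
# constant offset of the first channel
tiny_patch_problem <- function(n_per_class = 60L, k = 5L, d = 3L, seed = 7L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * k * k * d, sd = 0.3), n)
  lab <- rep(1:2, each = n_per_class)
  X[lab == 2L, seq_len(k * k)] <- X[lab == 2L, seq_len(k * k)] + 1.5
  structure(list(patches = X,
                 centers = cbind(rep(1L, n), seq_len(n)),
                 labels = lab, k = k, d = d,
                 source_shape = c(1L, n)),
            class = "patch_set")
}
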