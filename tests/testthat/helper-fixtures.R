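# Shared fixtures: small models and configurations built in code.

tiny_model <- function(seed = 5L, l_max = 1L, use_improper = FALSE) {
  rgc_model(model_config(n_blocks = 2L, hidden_dim = 16L, n_heads = 2L,
                         n_rbf = 8L, l_max = l_max,
                         use_improper = use_improper),
            seed = seed)
}

# central finite-difference forces of any energy function
fd_forces <- function(energy_fn, config, h = 1e-4) {
  n <- length(config$atomic_numbers)
  out <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    for (j in 1:3) {
      cp <- config; cp$coordinates[i, j] <- cp$coordinates[i, j] + h
      cm <- config; cm$coordinates[i, j] <- cm$coordinates[i, j] - h
      out[i, j] <- -(energy_fn(cp) - energy_fn(cm)) / (2 * h)
    }
  }
  out
}

random_unit <- function() {
  u <- stats::rnorm(3)
  u / sqrt(sum(u^2))
}

# simple harmonic diatomic used across MD tests
diatomic_spec <- function(k = 100, r0 = 1) {
  toy_potential_spec(atomic_numbers = c(6L, 6L),
                     coordinates = rbind(c(0, 0, 0), c(r0, 0, 0)),
                     bonds = data.frame(i = 1L, j = 2L, k = k, r0 = r0))
}
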