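# Shared fixtures: everything is generated in code at test time.

quick_config <- function(...) {
  args <- list(proj_dim = 8L, head_dim = 16L, tokens = 2L, max_epochs = 25L,
               patience = 10L, learning_rate = 5e-3, l2_strength = 1e-3,
               dropout = 0.2, q_steps = 2L, temporal_channels = 8L)
  user <- list(...)
  args[names(user)] <- user
  do.call(ddf_config, args)
}

small_table <- function(n = 300, seed = 1, ...) {
  generate_classification(synthetic_spec(
    n_samples = n, dim_common = 4, dim_specific_a = 2, dim_specific_b = 2,
    dim_modality_a = 8, dim_modality_b = 8, seed = seed, ...))
}

# literal double-loop vCLUB reference (independent of the vectorised path)
club_reference <- function(a, b, q) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  fw <- ddfusion:::q_forward(q, a)
  loglik <- function(i, j) {
    sum(stats::dnorm(b[j, ], mean = fw$mu[i, ], sd = exp(fw$lv[i, ] / 2),
                     log = TRUE))
  }
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    total <- total + loglik(i, i) - loglik(i, j)
  }
  total / n^2
}
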