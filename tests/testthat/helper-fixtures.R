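# Shared fixture builders; everything is generated in code at test time.

quick_mcmc <- function(seed = 1L, n_iter = 800L, burn_in = 300L, thin = 2L) {
  mcmc_settings(n_iter, burn_in, thin, seed)
}

# Small two-cycle dataset with configurable structure.
small_dataset <- function(seed = 1L, n_train = 60L, n_test = 30L,
                          n_markers = 300L, n_traits = 2L,
                          h2 = 0.5, gcor = 0.3, gxe_var = 0) {
  sg <- rep(h2, n_traits)
  S_T <- diag(sg, n_traits)
  if (n_traits > 1L) {
    S_T[upper.tri(S_T)] <- S_T[lower.tri(S_T)] <- gcor * h2
  }
  simulate_dataset(sim_config(
    n_train_lines = n_train, n_test_lines = n_test, n_markers = n_markers,
    n_traits = n_traits, sigma_T = S_T,
    sigma_TE = diag(gxe_var, n_traits),
    residual_cov = diag(1 - h2 - gxe_var, n_traits),
    seed = seed))
}

lines_of_cycle <- function(d, env) names(d$cycles)[d$cycles == env]

observed_values <- function(d, trait, lines) {
  ph <- d$phenotypes
  v <- ph[ph$trait == trait, ]
  stats::setNames(v$value, v$line)[lines]
}
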