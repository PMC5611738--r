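# Shared fixtures: small synthetic cohorts and toy matrices, built in code.

# A small default-mix cohort used by several module tests.
small_cohort <- function(seed = 42, ...) {
  simulate_cohort(sim_config(
    n_cpgs_per_class = c(concordant = 300, discordant = 300, invariant = 120,
                         polymorphic = 100, sex_linked = 60, cell_driven = 120),
    seed = seed, ...))
}

# Noise-free, batch-free cohort: deterministic class signals.
noisefree_cohort <- function(seed = 7, strength = 1, ...) {
  simulate_cohort(sim_config(
    n_cpgs_per_class = c(concordant = 100, discordant = 100, invariant = 40,
                         polymorphic = 40, sex_linked = 20, cell_driven = 60),
    noise_sd = 0, batch_sd = 0, concordance_strength = strength,
    seed = seed, ...))
}

# Toy beta matrix with named probes/samples.
toy_betas <- function(n_probes = 10, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.05, 0.95), nrow = n_probes,
              dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                              sprintf("samp%02d", seq_len(n_samples))))
  m
}

# Truth classes aligned to a probe-id vector.
truth_class <- function(cohort, probe_ids) {
  unname(cohort$truth$class[probe_ids])
}
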