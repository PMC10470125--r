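# Fixture builders shared across test files. Everything is generated in
# code from a seed; nothing is read from disk.

# complete analytic table on the ln scale (truth, no censoring): fast
# input for model-fitting tests
make_complete_table <- function(seed = 1, betas = numeric(0),
                                n_cases = 144, n_controls = 1082,
                                n_source = 20000) {
  co <- generate_cohort(
    outcome_spec = default_outcome_spec(betas = betas, n_cases = n_cases,
                                        n_controls = n_controls),
    seed = seed, n_source = n_source)
  d <- co$truth
  for (m in metal_names()) d[[m]] <- log(d[[m]])
  d$eta <- NULL
  d
}

# full synthetic cohort (batch effects, censoring, missingness) at a
# reduced sample size
make_small_cohort <- function(seed = 1, n_cases = 60, n_controls = 300,
                              betas = numeric(0)) {
  simulate_cohort(
    seed = seed,
    outcome_spec = default_outcome_spec(betas = betas, n_cases = n_cases,
                                        n_controls = n_controls),
    n_source = 15000)
}

# named IQR vector of all ones, for closed-form OR checks
unit_iqr <- function() stats::setNames(rep(1, 11), metal_names())
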