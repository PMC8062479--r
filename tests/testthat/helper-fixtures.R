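# Shared fixtures: tiny schemes and fast CRM parameter sets.

scheme8 <- function(total_carbon = 1.5) {
  build_hierarchical_scheme(resource_set(sprintf("cs%d", 1:8), 1:8),
                            total_carbon)
}

scheme32 <- function(total_carbon = 1.5) {
  build_hierarchical_scheme(resource_set(sprintf("cs%02d", 1:32), 1:32),
                            total_carbon)
}

# Small, fast parameter set: coarse dynamics on a toy scale, for tests that
# exercise plumbing rather than the experimental regime.
fast_params <- function(...) {
  base <- list(w = 10, N0 = 1, R_total0 = 1.5, m = 0.05, k = 5,
               uptake_scale = 1, dt = 0.01, passage_interval = 8,
               n_passages = 2)
  do.call(crm_params, utils::modifyList(base, list(...)))
}

# Uptake matrix with fully specified entries (no randomness).
fixed_uptake <- function(C, M_primary = ncol(C), uptake_scale = max(C)) {
  structure(list(C = C, theta = rep(NA_real_, nrow(C)),
                 M_primary = M_primary,
                 M_byproduct = ncol(C) - M_primary,
                 uptake_scale = uptake_scale),
            class = "uptake_matrix")
}
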