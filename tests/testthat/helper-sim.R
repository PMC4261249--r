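# Shared fixtures for the simulation tests.

# Pure Poisson configuration: every variance component off.
theory_cfg <- function(lambda, n = 20000L, m = 8L, seed = NULL) {
  sim_config(lambda_true = lambda, n_created = n, m = m, seed = seed)
}

# Per-replicate point estimates, for replicate-set fixtures.
per_replicate_lambdas <- function(reps) {
  -log(reps$k_negative / reps$n_returned)
}

# A small counts CSV in the session temp dir; returns its path.
write_counts_fixture <- function(n_returned, k_negative,
                                 replicate_id = seq_along(n_returned),
                                 path = tempfile(fileext = ".csv")) {
  utils::write.csv(
    data.frame(replicate_id = replicate_id, n_returned = n_returned,
               k_negative = k_negative),
    path, row.names = FALSE, quote = FALSE)
  path
}
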