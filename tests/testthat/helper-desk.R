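# desk-scale synthetic benchmark shared across tests: a compact four-chain
# 600-residue assembly with 60 simulated crosslinks, candidate resolutions
# spanning 600 to 12 beads.  Computed once per test session.

.desk <- new.env()

desk_chains <- function() {
  data.frame(chain_id = c("A", "B", "C", "D"), length = c(150, 150, 150, 150))
}

desk_crosslinks <- function() {
  if (is.null(.desk$xl)) {
    ref <- generate_reference_assembly(desk_chains(), compactness = 1,
                                       seed = 42)
    .desk$xl <- simulate_crosslinks(ref, n = 60, cutoff = 25, fp_rate = 0.1,
                                    seed = 42)
  }
  .desk$xl
}

desk_ns_config <- function(n_live = 25) {
  ns_config(n_live = n_live, max_iterations = 120, max_attempts = 12,
            max_consecutive_failures = 8, max_plateau_hits = 15)
}

desk_fit <- function() {
  if (is.null(.desk$fit))
    .desk$fit <- nsrep(desk_chains(), desk_crosslinks(),
                       candidates = c(1, 5, 20, 50), n_runs = 3, seed = 42,
                       moves = move_set(n_steps_per_sample = 30),
                       ns = desk_ns_config())
  .desk$fit
}
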