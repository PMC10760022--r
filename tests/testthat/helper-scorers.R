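# analytic scorers for the nested-sampling contract

# uniform prior on [lower, upper] with an arbitrary log-likelihood
uniform_scorer <- function(loglik, lower = 0, upper = 1) {
  list(sample_prior = function() stats::runif(1, lower, upper),
       log_likelihood = loglik)
}

constant_scorer <- function(logl0) {
  list(sample_prior = function() stats::runif(1),
       log_likelihood = function(s) logl0)
}

# 1-D toy: uniform prior on [0, 10], Gaussian log-likelihood peaked at 5
gauss_toy_scorer <- function(shift = 0) {
  uniform_scorer(function(x) -(x - 5)^2 / 2 + shift, 0, 10)
}

# independent oracle for the toy evidence: adaptive quadrature of the
# 1-D integral (never the nested-sampling path)
gauss_toy_truth <- function() {
  q <- stats::integrate(function(x) exp(-(x - 5)^2 / 2), 0, 10)
  list(log_evidence = log(q$value / 10), rel_error = q$abs.error / q$value)
}

# 2-bead structural toy: one 10-residue chain at 5 residues/bead, a single
# crosslink between the beads, chain connectivity only (excluded volume off)
two_bead_toy <- function() {
  chains <- data.frame(chain_id = "A", length = 10)
  topo <- build_representation(chains, 5)
  xl <- data.frame(protein1 = "A", residue1 = 2, protein2 = "A", residue2 = 8)
  k_conn <- 0.1
  config <- restraint_config(likelihood_crosslinks = xl,
                             k_ev = 0, k_conn = k_conn)
  moves <- move_set(bead_step = 5, n_steps_per_sample = 250)
  list(topology = topo, config = config, moves = moves, k_conn = k_conn,
       rest_length = sum(topo$beads$radius))
}

# dense-grid oracle for the toy: the bead separation r has induced radial
# density r^2 exp(-k/2 max(0, r - rest)^2); the evidence is the likelihood
# averaged under it
two_bead_grid_oracle <- function(toy) {
  r <- seq(1e-4, 60, by = 0.005)
  w <- r^2 * exp(-toy$k_conn / 2 * pmax(0, r - toy$rest_length)^2)
  p <- toy$config$omega + (1 - toy$config$omega) /
    (1 + exp((r - toy$config$d0) / toy$config$slope))
  list(log_evidence = log(sum(w * p) / sum(w)),
       mean_sep = sum(w * r) / sum(w),
       var_sep = sum(w * r^2) / sum(w) - (sum(w * r) / sum(w))^2)
}
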