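## sampler module: Metropolis Monte Carlo on the modified prior.
##
## Nested sampling only needs approximately independent draws from the
## modified prior (optionally above a likelihood threshold).  Each draw is a
## fresh bond-respecting random initialization followed by a short
## single-temperature Metropolis chain; proposals translate one flexible bead
## or translate-and-rotate one rigid body, so the proposal is symmetric and
## detailed balance holds.  A replica-exchange ladder could be layered on top
## of `sample_from_modified_prior()` without touching the nested-sampling
## loop; at the problem scales targeted here the modified prior is mild
## enough for single-temperature chains.

#' Monte Carlo move parameters
#'
#' @param bead_step isotropic Gaussian translation scale for one flexible
#'   bead (A).
#' @param rb_trans_step rigid-body translation scale (A).
#' @param rb_rot_step rigid-body rotation scale about a random axis through
#'   the body centroid (radians).
#' @param n_steps_per_sample Metropolis steps per prior draw; enough steps
#'   must be taken that successive draws are approximately independent.
#' @return an object of class `"move_set"`.
#' @export
move_set <- function(bead_step = 3, rb_trans_step = 3, rb_rot_step = 0.3,
                     n_steps_per_sample = 50) {
  structure(list(bead_step = check_number(bead_step, "bead_step", 0),
                 rb_trans_step = check_number(rb_trans_step, "rb_trans_step", 0),
                 rb_rot_step = check_number(rb_rot_step, "rb_rot_step", 0),
                 n_steps_per_sample = check_count(n_steps_per_sample,
                                                 "n_steps_per_sample", 0)),
            class = "move_set")
}

#' Random initial model
#'
#' Places each chain by a bond-respecting random walk: the first bead of a
#' chain lands uniformly inside a bounding sphere, and every following bead
#' sits at touching distance (sum of radii) from its predecessor in a random
#' direction, resampled to stay inside the sphere.  The sphere radius is
#' `box_scale` times the volume-equivalent radius of the whole assembly, so
#' the starting density is comparable across representations of the same
#' assembly.
#'
#' @param topology a [build_representation()].
#' @param box_scale bounding-sphere radius in units of the assembly's
#'   volume-equivalent radius.
#' @return a [structure_model()].
#' @export
random_model <- function(topology, box_scale = 3) {
  stopifnot(inherits(topology, "bead_topology"))
  R <- box_scale * bead_radius(sum(topology$chain_len))
  b <- topology$beads
  n <- topology$n_beads
  coords <- matrix(0, n, 3)
  uniform_in_ball <- function(r) {
    repeat {
      p <- stats::runif(3, -r, r)
      if (sum(p * p) <= r * r) return(p)
    }
  }
  idx_by_chain <- split(seq_len(n), b$chain_id)
  for (idx in idx_by_chain) {
    coords[idx[1], ] <- uniform_in_ball(R)
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        bond <- b$radius[idx[k - 1]] + b$radius[idx[k]]
        for (try in 1:50) {
          p <- coords[idx[k - 1], ] + bond * random_unit_vector()
          if (sum(p * p) <= R * R) break
        }
        coords[idx[k], ] <- p
      }
    }
  }
  new_structure_model(coords, topology)
}

## internal proposal on a raw coordinate matrix; unit u indexes flexible
## beads first, rigid bodies after
propose_coords <- function(coords, topo, moves, flex_idx, rb_list) {
  n_units <- length(flex_idx) + length(rb_list)
  u <- if (n_units == 1) 1L else sample.int(n_units, 1L)
  if (u <= length(flex_idx)) {
    i <- flex_idx[u]
    coords[i, ] <- coords[i, ] + stats::rnorm(3, 0, moves$bead_step)
  } else {
    idx <- rb_list[[u - length(flex_idx)]]
    block <- coords[idx, , drop = FALSE]
    centroid <- colMeans(block)
    rot <- rotation_matrix(random_unit_vector(),
                           stats::rnorm(1, 0, moves$rb_rot_step))
    shift <- centroid + stats::rnorm(3, 0, moves$rb_trans_step)
    coords[idx, ] <- sweep(sweep(block, 2, centroid) %*% t(rot), 2, shift, "+")
  }
  coords
}

#' Propose one Monte Carlo move
#'
#' Translates one randomly chosen flexible bead by an isotropic Gaussian
#' step, or translates and rotates one rigid body about its centroid.  The
#' proposal is symmetric; the input model is not modified.
#'
#' @param model a [structure_model()].
#' @param moves a [move_set()].
#' @return the proposed [structure_model()].
#' @export
propose_move <- function(model, moves) {
  stopifnot(inherits(model, "structure_model"), inherits(moves, "move_set"))
  topo <- model$topology
  new_structure_model(
    propose_coords(model$coordinates, topo, moves,
                   which(topo$beads$flexible), topo$rigid_bodies),
    topo)
}

## score context: everything the hot loop needs, resolved once per
## (topology, config) pair so per-step work is pure arithmetic
make_score_context <- function(topology, config) {
  map_set <- function(xl) {
    if (is.null(xl) || nrow(xl) == 0) return(list(i = integer(0), j = integer(0)))
    what <- sprintf("crosslink %s:%s--%s:%s", xl$protein1, xl$residue1,
                    xl$protein2, xl$residue2)
    list(i = as.integer(mapply(function(p, r, w) residue_to_bead(topology, p, r, w),
                               xl$protein1, xl$residue1, what)),
         j = as.integer(mapply(function(p, r, w) residue_to_bead(topology, p, r, w),
                               xl$protein2, xl$residue2, what)))
  }
  rb_id <- integer(topology$n_beads)
  for (k in seq_along(topology$rigid_bodies))
    rb_id[topology$rigid_bodies[[k]]] <- k
  list(topology = topology,
       flex_idx = which(topology$beads$flexible),
       rb_list = lapply(topology$rigid_bodies, as.integer),
       rb_id = rb_id,
       radius = topology$beads$radius,
       prior_xl = map_set(config$prior_crosslinks),
       lik_xl = map_set(config$likelihood_crosslinks),
       d0 = config$d0, slope = config$slope, omega = config$omega,
       k_ev = config$k_ev, k_conn = config$k_conn)
}

ctx_log_modified_prior <- function(coords, ctx) {
  ev_penalty(coords, ctx$topology, ctx$k_ev) +
    conn_penalty(coords, ctx$topology, ctx$k_conn) +
    xl_loglik_pairs(coords, ctx$prior_xl$i, ctx$prior_xl$j,
                    ctx$d0, ctx$slope, ctx$omega)
}

ctx_log_likelihood <- function(coords, ctx) {
  xl_loglik_pairs(coords, ctx$lik_xl$i, ctx$lik_xl$j,
                  ctx$d0, ctx$slope, ctx$omega)
}

## Metropolis core: compiled kernel (full rescoring per proposal, R RNG)
ctx_mcmc <- function(coords, ctx, moves, n_steps) {
  if (n_steps == 0)
    return(list(coords = coords,
                log_modified_prior = ctx_log_modified_prior(coords, ctx),
                accepted = 0L))
  conn <- ctx$topology$conn
  .mcmc_kernel_cpp(coords, as.integer(n_steps),
                   as.integer(ctx$flex_idx), ctx$rb_list,
                   ctx$radius, ctx$rb_id,
                   as.integer(conn$i), as.integer(conn$j),
                   as.numeric(conn$rest),
                   ctx$prior_xl$i, ctx$prior_xl$j,
                   ctx$d0, ctx$slope, ctx$omega, ctx$k_ev, ctx$k_conn,
                   moves$bead_step, moves$rb_trans_step, moves$rb_rot_step)
}

## pure-R reference of the same kernel; used to cross-validate the compiled
## path in the test suite
ctx_mcmc_r <- function(coords, ctx, moves, n_steps) {
  lp <- ctx_log_modified_prior(coords, ctx)
  accepted <- 0L
  for (s in seq_len(n_steps)) {
    prop <- propose_coords(coords, ctx$topology, moves, ctx$flex_idx,
                           ctx$rb_list)
    lpp <- ctx_log_modified_prior(prop, ctx)
    if (lpp - lp > log(stats::runif(1))) {
      coords <- prop
      lp <- lpp
      accepted <- accepted + 1L
    }
  }
  list(coords = coords, log_modified_prior = lp, accepted = accepted)
}

#' Draw from the modified prior by Metropolis MCMC
#'
#' Runs `n_steps_per_sample` Metropolis steps with acceptance probability
#' `min(1, exp(delta log modified prior))` starting from `initial`.
#'
#' @param initial starting [structure_model()].
#' @param config a [restraint_config()].
#' @param moves a [move_set()].
#' @return list with `model` (final state), `steps`, `accept_rate`,
#'   `elapsed` (seconds) and `per_step_time` (seconds per Metropolis step).
#' @export
sample_from_modified_prior <- function(initial, config, moves = move_set()) {
  stopifnot(inherits(initial, "structure_model"),
            inherits(config, "restraint_config"))
  ctx <- make_score_context(initial$topology, config)
  t0 <- proc.time()[["elapsed"]]
  out <- ctx_mcmc(initial$coordinates, ctx, moves, moves$n_steps_per_sample)
  elapsed <- proc.time()[["elapsed"]] - t0
  list(model = new_structure_model(out$coords, initial$topology),
       steps = moves$n_steps_per_sample,
       accept_rate = if (moves$n_steps_per_sample > 0)
         out$accepted / moves$n_steps_per_sample else NA_real_,
       elapsed = elapsed,
       per_step_time = elapsed / max(1L, moves$n_steps_per_sample))
}

#' Draw from the constrained modified prior
#'
#' Repeatedly draws fresh models from the modified prior (random
#' initialization + Metropolis) and returns the first whose log-likelihood
#' under the likelihood crosslinks is strictly greater than `threshold`.
#'
#' @param initial starting [structure_model()] for every attempt.
#' @param config a [restraint_config()].
#' @param threshold log-likelihood bound; `-Inf` accepts the first draw.
#' @param moves a [move_set()].
#' @param max_attempts consecutive rejected draws before giving up.
#' @return list with `model` and `attempts` on success; `NULL` on failure
#'   (a value, consumed by the nested-sampling convergence logic).
#' @export
constrained_sample <- function(initial, config, threshold,
                               moves = move_set(), max_attempts = 50) {
  max_attempts <- check_count(max_attempts, "max_attempts")
  stopifnot(inherits(initial, "structure_model"),
            inherits(config, "restraint_config"))
  for (a in seq_len(max_attempts)) {
    draw <- sample_from_modified_prior(initial, config, moves)
    ll <- crosslink_loglik(draw$model, config$likelihood_crosslinks,
                           config$d0, config$slope, config$omega)
    if (ll > threshold) return(list(model = draw$model, attempts = a,
                                    log_likelihood = ll))
  }
  NULL
}
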