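## nested_sampling module: the core loop.
##
## Nested sampling turns the evidence integral Z = int L(theta) pi(theta)
## dtheta into the one-dimensional integral Z = int_0^1 L(X) dX over prior
## mass X (the fraction of prior with likelihood above a threshold).  A
## population of n_live prior draws ("live points") is maintained; at each
## iteration the worst live point dies at estimated mass X_i = exp(-i /
## n_live) and is replaced by a draw from the prior constrained to exceed its
## likelihood.  The evidence accumulates by rectangle-rule quadrature over
## the dead points plus a remainder term from the surviving live points.
## Runs terminate when constrained sampling keeps failing, when fresh samples
## keep landing on a likelihood plateau, or at an iteration cap.

#' Nested-sampling configuration
#'
#' @param n_live number of live points (>= 2); should be at least the number
#'   of free parameters of the representation (see
#'   [count_free_parameters()]).
#' @param max_iterations hard cap on iterations, set high so runs normally
#'   converge through the two counters below.
#' @param max_consecutive_failures consecutive constrained-sampling failures
#'   (each one `max_attempts` rejected draws) that terminate a run.
#' @param max_plateau_hits consecutive likelihood-plateau detections that
#'   terminate a run.
#' @param max_attempts rejected draws per constrained-sampling round.
#' @param seed integer RNG seed for the run, or `NULL`.
#' @return an object of class `"ns_config"`.
#' @export
ns_config <- function(n_live = 50, max_iterations = 10000,
                      max_consecutive_failures = 20, max_plateau_hits = 20,
                      max_attempts = 50, seed = NULL) {
  structure(list(
    n_live = check_count(n_live, "n_live", 2),
    max_iterations = check_count(max_iterations, "max_iterations"),
    max_consecutive_failures = check_count(max_consecutive_failures,
                                           "max_consecutive_failures"),
    max_plateau_hits = check_count(max_plateau_hits, "max_plateau_hits"),
    max_attempts = check_count(max_attempts, "max_attempts"),
    seed = if (is.null(seed)) NULL else check_count(seed, "seed", 0)),
    class = "ns_config")
}

#' Deterministic prior-mass estimate
#'
#' The standard shrinkage estimate `X_i = exp(-i / n_live)` for the prior
#' mass remaining after `i` iterations; `X_0 = 1` and `X` is strictly
#' decreasing in `i`.
#'
#' @param i iteration index (vectorized, >= 0).
#' @param n_live number of live points.
#' @return prior-mass fraction(s) in `(0, 1]`.
#' @export
prior_mass <- function(i, n_live) {
  if (any(i < 0)) stop("'i' must be >= 0", call. = FALSE)
  n_live <- check_number(n_live, "n_live", 0, strict = TRUE)
  exp(-i / n_live)
}

#' Likelihood-plateau test
#'
#' A fresh sample sits on a likelihood plateau when its likelihood grows
#' slower than the prior mass shrinks: `L_next / L_i < X_i / X_next`,
#' evaluated in log space with a strict inequality.
#'
#' @param logl_i,logl_next log-likelihoods of successive samples.
#' @param x_i,x_next their prior masses, `x_i > x_next > 0`.
#' @return logical.
#' @export
check_plateau <- function(logl_i, logl_next, x_i, x_next) {
  if (!is.finite(logl_i) || !is.finite(logl_next))
    stop("log-likelihoods must be finite", call. = FALSE)
  if (!(x_i > x_next) || !(x_next > 0))
    stop("need x_i > x_next > 0", call. = FALSE)
  (logl_next - logl_i) < (log(x_i) - log(x_next))
}

#' Integrate the evidence from a likelihood trace
#'
#' Rectangle-rule quadrature of the L-versus-X curve: each dead point
#' contributes `L_i * (X_{i-1} - X_i)` with `X_i = exp(-i / n_live)`, and the
#' surviving live points contribute the remainder
#' `mean(L_live) * X_final`.  With the remainder term the quadrature weights
#' sum to exactly 1, so a constant likelihood integrates to itself.  All
#' arithmetic is in log space.
#'
#' @param dead_log_likelihoods non-decreasing log-likelihoods of dead points,
#'   in removal order.
#' @param live_log_likelihoods log-likelihoods of the live points at
#'   termination.
#' @param n_live number of live points used for the shrinkage estimate.
#' @return the log-evidence, a single numeric.
#' @export
integrate_evidence <- function(dead_log_likelihoods, live_log_likelihoods,
                               n_live) {
  k <- length(dead_log_likelihoods)
  m <- length(live_log_likelihoods)
  if (k == 0 && m == 0)
    stop("no likelihood values to integrate", call. = FALSE)
  n_live <- check_number(n_live, "n_live", 0, strict = TRUE)
  x <- exp(-(0:k) / n_live)
  terms <- numeric(0)
  if (k > 0)
    terms <- dead_log_likelihoods + log(x[1:k] - x[2:(k + 1)])
  if (m > 0)
    terms <- c(terms, live_log_likelihoods - log(m) + log(x[k + 1]))
  logsumexp(terms)
}

#' Run one nested-sampling estimate of the evidence
#'
#' `scorer` is any list exposing the sampling contract:
#' \describe{
#'   \item{`sample_prior()`}{returns one approximately independent draw
#'     (an arbitrary state object) from the modified prior;}
#'   \item{`log_likelihood(state)`}{its log-likelihood;}
#'   \item{`steps_per_sample`}{optional: MCMC steps behind each draw
#'     (default 1), used for per-step timing.}
#'   \item{`step_stats()`}{optional: returns `list(elapsed, steps)` for the
#'     time spent inside the Metropolis kernel, giving an exact per-step
#'     timing; without it the whole-run wall time is divided by the total
#'     step count.}
#' }
#' [structural_scorer()] builds this contract for bead models; analytic test
#' problems can supply their own.
#'
#' Each iteration records the worst live point as dead at mass
#' `exp(-i / n_live)` and replaces it with a constrained draw (fresh prior
#' draws rejected until one exceeds the dying likelihood).  The plateau test
#' is applied to the last candidate generated in each iteration, accepted or
#' not, so a likelihood that has gone flat is detected even while constrained
#' draws keep failing; the plateau counter is checked before the failure
#' counter.
#'
#' @param scorer the sampling contract above.
#' @param config an [ns_config()].
#' @return an object of class `"ns_result"`: log-evidence, the dead-point
#'   log-likelihood trace, termination reason (`"failure-limit"`,
#'   `"plateau-limit"` or `"max-iterations"`), iteration count, and the mean
#'   wall time per MCMC step.
#' @export
ns_run <- function(scorer, config = ns_config()) {
  stopifnot(is.list(scorer), is.function(scorer$sample_prior),
            is.function(scorer$log_likelihood), inherits(config, "ns_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  steps_per <- scorer$steps_per_sample %||% 1
  t0 <- Sys.time()
  n_live <- config$n_live

  live <- vector("list", n_live)
  logl <- numeric(n_live)
  draws <- 0L
  for (k in seq_len(n_live)) {
    st <- NULL
    for (a in seq_len(config$max_attempts)) {
      st <- tryCatch(scorer$sample_prior(), error = function(e) NULL)
      draws <- draws + 1L
      if (!is.null(st)) break
    }
    if (is.null(st))
      stop(errorCondition(
        sprintf("nested-sampling run failed: could not draw initial live point %d", k),
        class = c("nsrep_run_failure", "error", "condition")))
    live[[k]] <- st
    logl[k] <- scorer$log_likelihood(st)
  }

  dead <- numeric(0)
  fail_count <- 0L
  plateau_count <- 0L
  termination <- "max-iterations"
  log_shrink <- 1 / n_live  # log(X_i / X_{i+1}) under deterministic shrinkage

  while (length(dead) < config$max_iterations) {
    w <- which.min(logl)  # ties broken by lowest bead/live index
    threshold <- logl[w]
    new_state <- NULL
    last_ll <- NA_real_
    for (a in seq_len(config$max_attempts)) {
      cand <- scorer$sample_prior()
      draws <- draws + 1L
      last_ll <- scorer$log_likelihood(cand)
      if (last_ll > threshold) {
        new_state <- cand
        break
      }
    }

    plateau_hit <- is.finite(last_ll) && is.finite(threshold) &&
      (last_ll - threshold) < log_shrink
    plateau_count <- if (plateau_hit) plateau_count + 1L else 0L

    if (!is.null(new_state)) {
      dead <- c(dead, threshold)
      live[[w]] <- new_state
      logl[w] <- last_ll
      fail_count <- 0L
    } else {
      fail_count <- fail_count + 1L
    }

    if (plateau_count >= config$max_plateau_hits) {
      termination <- "plateau-limit"
      break
    }
    if (fail_count >= config$max_consecutive_failures) {
      termination <- "failure-limit"
      break
    }
  }

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ## sampling efficiency: mean wall time per MCMC step.  Scorers that track
  ## their Metropolis kernel report it exactly; otherwise the whole-run time
  ## (including bookkeeping) is divided by the number of steps.
  per_step <- if (is.function(scorer$step_stats)) {
    st <- scorer$step_stats()
    if (st$steps > 0 && st$elapsed > 0) st$elapsed / st$steps
    else elapsed / max(1, draws * steps_per)
  } else elapsed / max(1, draws * steps_per)
  structure(list(
    log_evidence = integrate_evidence(dead, logl, n_live),
    dead_log_likelihoods = dead,
    live_log_likelihoods = logl,
    termination = termination,
    iterations = length(dead),
    n_draws = draws,
    per_step_time = per_step,
    elapsed = elapsed,
    seed = config$seed,
    config = config),
    class = "ns_result")
}

#' @export
print.ns_result <- function(x, ...) {
  cat(sprintf(paste0("Nested-sampling run: log Z = %.4f\n",
                     "  %d iterations, terminated by %s; %.2e s/MCMC step\n"),
              x$log_evidence, x$iterations, x$termination, x$per_step_time))
  invisible(x)
}

#' Write a run result as JSON
#'
#' @param result an [ns_run()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ns_result <- function(result, file) {
  stopifnot(inherits(result, "ns_result"))
  cfg <- result$config
  jsonlite::write_json(list(
    log_evidence = result$log_evidence,
    termination = result$termination,
    iterations = result$iterations,
    per_step_time = result$per_step_time,
    dead_log_likelihoods = result$dead_log_likelihoods,
    seed = result$seed,
    config = cfg[c("n_live", "max_iterations", "max_consecutive_failures",
                   "max_plateau_hits", "max_attempts")]),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Build the nested-sampling scorer for a bead representation
#'
#' Packages a topology, a repartitioned restraint configuration and a move
#' set into the sampling contract consumed by [ns_run()]: every prior draw is
#' a fresh [random_model()] evolved by `n_steps_per_sample` Metropolis steps
#' under the modified prior.
#'
#' @param topology a [build_representation()].
#' @param config a [restraint_config()].
#' @param moves a [move_set()].
#' @return a scorer list (see [ns_run()]).
#' @export
structural_scorer <- function(topology, config, moves = move_set()) {
  stopifnot(inherits(topology, "bead_topology"),
            inherits(config, "restraint_config"))
  ctx <- make_score_context(topology, config)
  kernel_time <- 0
  kernel_steps <- 0L
  list(
    sample_prior = function() {
      init <- random_model(topology)
      t0 <- proc.time()[["elapsed"]]
      out <- ctx_mcmc(init$coordinates, ctx, moves, moves$n_steps_per_sample)
      kernel_time <<- kernel_time + (proc.time()[["elapsed"]] - t0)
      kernel_steps <<- kernel_steps + moves$n_steps_per_sample
      out$coords
    },
    log_likelihood = function(state) ctx_log_likelihood(state, ctx),
    ## wall time spent inside the Metropolis kernel, excluding chain
    ## re-initialization and nested-sampling bookkeeping
    step_stats = function() list(elapsed = kernel_time, steps = kernel_steps),
    steps_per_sample = max(1L, moves$n_steps_per_sample),
    topology = topology)
}
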