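## orchestrator module: many runs per candidate representation, collation,
## Bayes factors, and the optimal-representation selection rule.

#' Run nested sampling for every candidate representation
#'
#' Executes `n_runs` independent nested-sampling runs per candidate
#' residues-per-bead value, with per-run seeds derived deterministically from
#' `seed` (so results are identical for any `workers` count).  Runs that end
#' in a run-failure error are relaunched with a fresh seed up to `retry_cap`
#' times.  The crosslinks are split once into prior/likelihood sets and the
#' same split is used for every candidate, so evidences are comparable.
#'
#' @param chains chain table (see [read_topology()]).
#' @param crosslinks crosslink table (see [read_crosslinks()]).
#' @param candidates integer vector of residues-per-bead values.
#' @param n_runs independent runs per candidate.
#' @param prior_fraction fraction of crosslinks moved into the modified
#'   prior (see [repartition_restraints()]).
#' @param restraints named list overriding [restraint_config()] parameters
#'   (`d0`, `slope`, `omega`, `k_ev`, `k_conn`).
#' @param moves a [move_set()].
#' @param ns an [ns_config()]; its `seed` is ignored (per-run seeds are
#'   derived from `seed`).
#' @param seed master seed for the crosslink split and all runs.
#' @param workers parallel worker processes (forked; 1 = serial).
#' @param retry_cap relaunches per failed run.
#' @param scorer_factory optional `function(label, topology, config, moves)`
#'   returning an [ns_run()] scorer; defaults to [structural_scorer()].
#'   Intended for tests and analytic problems.
#' @param out_dir if non-`NULL`, per-run JSON files are written here.
#' @param verbose log per-run progress to stderr?
#' @return list with `collated` (one row per candidate: `label`,
#'   `mean_logZ`, `sem_logZ`, `mean_per_step_time`, `n_successful_runs`,
#'   `failed`), `runs` (per-candidate lists of [ns_run()] results),
#'   `partition` and `seed`.
#' @export
run_candidates <- function(chains, crosslinks, candidates, n_runs = 5,
                           prior_fraction = 0.3, restraints = list(),
                           moves = move_set(), ns = ns_config(), seed = 1,
                           workers = 1L, retry_cap = 2L,
                           scorer_factory = NULL, out_dir = NULL,
                           verbose = FALSE) {
  if (length(candidates) < 1) stop("need at least one candidate", call. = FALSE)
  n_runs <- check_count(n_runs, "n_runs")
  seed <- check_count(seed, "seed", 0)
  retry_cap <- check_count(retry_cap, "retry_cap", 0)

  part <- repartition_restraints(crosslinks, prior_fraction, seed = seed)
  rc_args <- c(list(prior_crosslinks = part$prior,
                    likelihood_crosslinks = part$likelihood), restraints)
  config <- do.call(restraint_config, rc_args)

  labels <- as.character(candidates)
  n_jobs <- length(candidates) * n_runs
  seed_pool <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_jobs * (retry_cap + 1L)),
           nrow = n_jobs))

  jobs <- expand.grid(run = seq_len(n_runs), cand = seq_along(candidates))
  make_scorer <- function(ci) {
    topo <- build_representation(chains, candidates[ci])
    if (is.null(scorer_factory)) structural_scorer(topo, config, moves)
    else scorer_factory(labels[ci], topo, config, moves)
  }

  run_one <- function(j) {
    ci <- jobs$cand[j]
    scorer <- make_scorer(ci)
    res <- NULL
    for (attempt in seq_len(retry_cap + 1L)) {
      run_seed <- seed_pool[j, attempt]
      cfg <- ns
      cfg$seed <- run_seed
      res <- tryCatch(ns_run(scorer, cfg),
                      nsrep_run_failure = function(e) NULL)
      if (!is.null(res)) break
      if (verbose)
        message(sprintf("[%s] run %d failed (attempt %d); relaunching",
                        labels[ci], jobs$run[j], attempt))
    }
    if (verbose && !is.null(res))
      message(sprintf("[%s] run %d: log Z = %.3f (%s, %d iterations)",
                      labels[ci], jobs$run[j], res$log_evidence,
                      res$termination, res$iterations))
    res
  }

  results <- if (workers > 1L)
    parallel::mclapply(seq_len(n_jobs), run_one, mc.cores = workers)
  else lapply(seq_len(n_jobs), run_one)

  runs <- lapply(seq_along(candidates), function(ci) {
    rr <- results[jobs$cand == ci]
    rr[!vapply(rr, is.null, TRUE)]
  })
  names(runs) <- labels

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ci in seq_along(candidates))
      for (k in seq_along(runs[[ci]]))
        write_ns_result(runs[[ci]][[k]],
                        file.path(out_dir, sprintf("run_%s_%02d.json",
                                                   labels[ci], k)))
  }

  collated <- do.call(rbind, lapply(seq_along(candidates), function(ci)
    collate_runs(runs[[ci]], labels[ci])))
  rownames(collated) <- NULL
  list(collated = collated, runs = runs, partition = part, seed = seed)
}

#' Collate one candidate's nested-sampling runs
#'
#' Mean and standard error (`sd / sqrt(n)`) of the log-evidence across
#' successful runs, and the mean wall time per MCMC step (the sampling
#' efficiency of the representation).
#'
#' @param runs list of [ns_run()] results (may be empty if every run
#'   failed).
#' @param label representation label, e.g. `"20"`.
#' @return one-row data frame.
#' @export
collate_runs <- function(runs, label) {
  if (length(runs) == 0)
    return(data.frame(label = label, mean_logZ = NA_real_,
                      sem_logZ = NA_real_, mean_per_step_time = NA_real_,
                      n_successful_runs = 0L, failed = TRUE))
  lz <- vapply(runs, function(r) r$log_evidence, 0)
  if (length(lz) == 1) {
    warning(sprintf("representation %s: single run; standard error reported as 0",
                    label), call. = FALSE)
    sem <- 0
  } else sem <- stats::sd(lz) / sqrt(length(lz))
  data.frame(label = label,
             mean_logZ = mean(lz),
             sem_logZ = sem,
             mean_per_step_time = mean(vapply(runs, function(r) r$per_step_time, 0)),
             n_successful_runs = length(lz),
             failed = FALSE)
}

#' Log Bayes factor between two representations
#'
#' Under equal prior probability for the two representations, the Bayes
#' factor is the evidence ratio, so its log is the difference of the mean
#' log-evidences.
#'
#' @param a,b rows of the collated table (or any list with `mean_logZ`).
#' @return `mean_logZ(a) - mean_logZ(b)`.
#' @export
log_bayes_factor <- function(a, b) {
  as.numeric(a$mean_logZ) - as.numeric(b$mean_logZ)
}

#' Select optimal representations
#'
#' Applies the two-criterion rule: (1) keep the sampling-efficient
#' candidates, whose mean per-step time is within `time_fold` of the fastest;
#' (2) among those, find the best mean evidence and call optimal every
#' efficient candidate whose `mean +/- sem_mult * SEM` evidence interval
#' overlaps the best one's.  A candidate with top evidence can therefore be
#' excluded purely on sampling cost.
#'
#' @param collated collated table from [run_candidates()] (or an `"nsrep"`
#'   fit).
#' @param time_fold efficiency tolerance (default threefold).
#' @param sem_mult half-width of the evidence interval in SEMs.
#' @return an object of class `"selection_report"` with `optimal`,
#'   `evidence_ranking`, `efficient_set` and per-candidate `rationale`.
#' @export
rank_representations <- function(collated, time_fold = 3, sem_mult = 1) {
  if (inherits(collated, "nsrep")) collated <- collated$collated
  collated <- as.data.frame(collated)
  ok <- !collated$failed & is.finite(collated$mean_logZ)
  if (!any(ok)) stop("no successful candidates to rank", call. = FALSE)
  cand <- collated[ok, , drop = FALSE]
  time_fold <- check_number(time_fold, "time_fold", 1)

  efficient <- cand$mean_per_step_time <=
    time_fold * min(cand$mean_per_step_time)
  eff <- cand[efficient, , drop = FALSE]
  best <- eff[which.max(eff$mean_logZ), , drop = FALSE]
  lo <- eff$mean_logZ - sem_mult * eff$sem_logZ
  hi <- eff$mean_logZ + sem_mult * eff$sem_logZ
  overlap <- lo <= (best$mean_logZ + sem_mult * best$sem_logZ) &
    hi >= (best$mean_logZ - sem_mult * best$sem_logZ)
  optimal <- eff$label[overlap]

  rationale <- character(nrow(collated))
  names(rationale) <- collated$label
  for (k in seq_len(nrow(collated))) {
    lab <- collated$label[k]
    rationale[k] <-
      if (!ok[k]) "failed: no successful runs"
      else if (!(lab %in% cand$label[efficient]))
        sprintf("excluded: per-step time %.3g s exceeds %g-fold of fastest (%.3g s)",
                collated$mean_per_step_time[k], time_fold,
                min(cand$mean_per_step_time))
      else if (!(lab %in% optimal))
        sprintf("excluded: evidence interval below best efficient candidate (%s)",
                best$label)
      else "optimal: efficient and evidence indistinguishable from best"
  }

  structure(list(optimal = optimal,
                 evidence_ranking = cand$label[order(cand$mean_logZ,
                                                     decreasing = TRUE)],
                 efficient_set = cand$label[efficient],
                 rationale = rationale,
                 best_efficient = best$label,
                 time_fold = time_fold,
                 sem_mult = sem_mult),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Representation selection\n")
  cat("  evidence ranking :", paste(x$evidence_ranking, collapse = " > "), "\n")
  cat(sprintf("  efficient set    : {%s}  (within %g-fold of fastest)\n",
              paste(x$efficient_set, collapse = ", "), x$time_fold))
  cat(sprintf("  optimal          : {%s}\n", paste(x$optimal, collapse = ", ")))
  for (lab in names(x$rationale))
    cat(sprintf("    %-6s %s\n", lab, x$rationale[[lab]]))
  invisible(x)
}

#' Robustness of the evidence ranking to the prior repartition
#'
#' Reruns the whole pipeline `n_repartitions` times with independent random
#' prior/likelihood crosslink splits and reports, per split, each candidate's
#' mean log-evidence, plus the Spearman rank correlation of the candidate
#' orderings between every pair of splits.  The output is descriptive: the
#' trend in evidence across candidates should be largely conserved across
#' priors, but no pass/fail threshold is imposed here.
#'
#' @inheritParams run_candidates
#' @param n_repartitions number of independent splits (>= 2).
#' @param ... further arguments passed to [run_candidates()].
#' @return an object of class `"nsrep_robustness"`: `table` (split x
#'   candidate mean/SEM), `cor_matrix` (pairwise Spearman), and
#'   `mean_correlation`.
#' @export
prior_robustness <- function(chains, crosslinks, candidates,
                             n_repartitions = 3, seed = 1, ...) {
  n_repartitions <- check_count(n_repartitions, "n_repartitions", 1)
  if (n_repartitions < 2)
    stop("'n_repartitions' must be >= 2 (nothing to compare)", call. = FALSE)
  split_seeds <- with_seed(seed,
    sample.int(.Machine$integer.max - 1L, n_repartitions))
  fits <- lapply(split_seeds, function(s)
    run_candidates(chains, crosslinks, candidates, seed = s, ...))
  tab <- do.call(rbind, lapply(seq_len(n_repartitions), function(k) {
    d <- fits[[k]]$collated
    data.frame(split = k, split_seed = split_seeds[k], label = d$label,
               mean_logZ = d$mean_logZ, sem_logZ = d$sem_logZ)
  }))
  z <- sapply(fits, function(f) f$collated$mean_logZ)
  cm <- stats::cor(z, method = "spearman", use = "pairwise.complete.obs")
  structure(list(table = tab, cor_matrix = cm,
                 mean_correlation = mean(cm[upper.tri(cm)]),
                 candidates = as.character(candidates)),
            class = "nsrep_robustness")
}

#' @export
print.nsrep_robustness <- function(x, ...) {
  cat(sprintf("Prior-repartition robustness: %d splits, candidates {%s}\n",
              max(x$table$split), paste(x$candidates, collapse = ", ")))
  print(x$table, row.names = FALSE)
  cat(sprintf("mean pairwise Spearman rank correlation of evidence: %.3f\n",
              x$mean_correlation))
  invisible(x)
}
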