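## Top-level fitting interface: one call from topology + crosslinks to a
## selection of optimal coarse-grained representations.

#' Select an optimal coarse-grained representation by nested sampling
#'
#' The main entry point.  For every candidate residues-per-bead value it
#' builds the bead representation, repartitions the crosslinks into a
#' modified prior and a likelihood, runs `n_runs` nested-sampling evidence
#' estimates, and applies the two-criterion selection rule (evidence and
#' sampling efficiency).
#'
#' @inheritParams run_candidates
#' @param time_fold,sem_mult selection-rule tolerances, see
#'   [rank_representations()].
#' @param ... further arguments passed to [run_candidates()]
#'   (`restraints`, `moves`, `ns`, `workers`, `retry_cap`, `out_dir`,
#'   `verbose`, ...).
#' @return an object of class `"nsrep"`: the collated evidence table
#'   (`$collated`), the per-run results (`$runs`), the crosslink partition
#'   (`$partition`) and the [rank_representations()] selection report
#'   (`$selection`).  Methods: `print`, `summary`, `plot`.
#' @export
#' @examples
#' chains <- data.frame(chain_id = c("A", "B"), length = c(40, 40))
#' ref <- generate_reference_assembly(chains, seed = 7)
#' xl <- simulate_crosslinks(ref, n = 20, seed = 7)
#' fit <- nsrep(chains, xl, candidates = c(10, 20),
#'              n_runs = 2, ns = ns_config(n_live = 8, max_iterations = 15,
#'                                         max_attempts = 5,
#'                                         max_consecutive_failures = 3,
#'                                         max_plateau_hits = 5),
#'              moves = move_set(n_steps_per_sample = 10), seed = 1)
#' fit
nsrep <- function(chains, crosslinks, candidates = c(1, 5, 20, 50),
                  n_runs = 5, prior_fraction = 0.3, seed = 1,
                  time_fold = 3, sem_mult = 1, ...) {
  cl <- match.call()
  out <- run_candidates(chains, crosslinks, candidates, n_runs = n_runs,
                        prior_fraction = prior_fraction, seed = seed, ...)
  out$selection <- rank_representations(out$collated, time_fold = time_fold,
                                        sem_mult = sem_mult)
  out$candidates <- as.character(candidates)
  out$call <- cl
  class(out) <- "nsrep"
  out
}

#' @export
print.nsrep <- function(x, digits = 4, ...) {
  cat("Representation selection by nested-sampling model evidence\n\n")
  d <- x$collated
  tab <- data.frame(residues_per_bead = d$label,
                    mean_logZ = round(d$mean_logZ, digits),
                    sem_logZ = signif(d$sem_logZ, 3),
                    s_per_step = signif(d$mean_per_step_time, 3),
                    n_runs = d$n_successful_runs)
  print(tab, row.names = FALSE)
  cat(sprintf("\nOptimal representation(s): {%s}\n",
              paste(x$selection$optimal, collapse = ", ")))
  invisible(x)
}

#' @export
summary.nsrep <- function(object, ...) {
  structure(list(fit = object), class = "summary.nsrep")
}

#' @export
print.summary.nsrep <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$selection)
  ok <- !x$fit$collated$failed
  if (sum(ok) > 1) {
    d <- x$fit$collated[ok, ]
    ref <- d[which.max(d$mean_logZ), ]
    cat("\nLog Bayes factors of the best-evidence representation",
        sprintf("(%s) over the others:\n", ref$label))
    for (k in seq_len(nrow(d)))
      if (d$label[k] != ref$label)
        cat(sprintf("  vs %-5s %8.3f\n", d$label[k],
                    log_bayes_factor(ref, d[k, ])))
  }
  invisible(x)
}

#' Evidence-versus-cost plot for a representation selection
#'
#' Mean log-evidence (with +/- 1 SEM error bars) against mean sampling time
#' per MCMC step, log-scaled time axis; optimal candidates are filled.
#'
#' @param x an [nsrep()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.nsrep <- function(x, ...) {
  d <- x$collated[!x$collated$failed, ]
  opt <- d$label %in% x$selection$optimal
  ylim <- range(d$mean_logZ - d$sem_logZ, d$mean_logZ + d$sem_logZ)
  graphics::plot(d$mean_per_step_time, d$mean_logZ, log = "x",
                 xlab = "sampling time per MCMC step (s)",
                 ylab = "mean log evidence", ylim = ylim,
                 pch = ifelse(opt, 19, 1), cex = 1.3, ...)
  graphics::arrows(d$mean_per_step_time, d$mean_logZ - d$sem_logZ,
                   d$mean_per_step_time, d$mean_logZ + d$sem_logZ,
                   angle = 90, code = 3, length = 0.04)
  graphics::text(d$mean_per_step_time, d$mean_logZ, labels = d$label,
                 pos = 4, offset = 0.4)
  graphics::legend("bottomright", pch = c(19, 1),
                   legend = c("optimal", "excluded"), bty = "n")
  invisible(x)
}

#' Read an experiment configuration
#'
#' YAML with keys `topology` (TSV path), `crosslinks` (CSV path),
#' `candidates`, and optional `n_runs`, `prior_fraction`, `seed`,
#' `restraints` (d0/slope/omega/k_ev/k_conn), `moves`
#' (bead_step/rb_trans_step/rb_rot_step/n_steps_per_sample) and `ns`
#' (n_live/max_iterations/max_consecutive_failures/max_plateau_hits/
#' max_attempts).  Relative data paths are resolved against the YAML's
#' directory.
#'
#' @param file path to the YAML file.
#' @return a named list of parsed settings.
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  for (key in c("topology", "crosslinks")) {
    if (is.null(cfg[[key]]))
      stop("config is missing '", key, "'", call. = FALSE)
    if (!file.exists(cfg[[key]]))
      cfg[[key]] <- file.path(dirname(normalizePath(file)), cfg[[key]])
  }
  if (is.null(cfg$candidates))
    stop("config is missing 'candidates'", call. = FALSE)
  cfg
}

#' Fit a representation selection from a configuration file
#'
#' @param config path to a YAML file, or the list [read_run_config()]
#'   returns.
#' @param workers parallel workers.
#' @param out_dir optional directory for per-run JSON output.
#' @param verbose log progress?
#' @return an [nsrep()] fit.
#' @export
nsrep_from_config <- function(config, workers = 1L, out_dir = NULL,
                              verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  chains <- read_topology(config$topology)
  xl <- read_crosslinks(config$crosslinks)
  nsrep(chains, xl,
        candidates = config$candidates,
        n_runs = config$n_runs %||% 5,
        prior_fraction = config$prior_fraction %||% 0.3,
        seed = config$seed %||% 1,
        time_fold = config$time_fold %||% 3,
        restraints = config$restraints %||% list(),
        moves = do.call(move_set, config$moves %||% list()),
        ns = do.call(ns_config, config$ns %||% list()),
        workers = workers, out_dir = out_dir, verbose = verbose)
}

#' Write the collated table and selection report of a fit
#'
#' Produces `<prefix>_collated.csv` (label, mean_logZ, sem_logZ,
#' mean_per_step_time, n_runs) and `<prefix>_selection.json`.
#'
#' @param fit an [nsrep()] fit.
#' @param prefix output path prefix.
#' @return the two paths, invisibly.
#' @export
write_nsrep <- function(fit, prefix) {
  stopifnot(inherits(fit, "nsrep"))
  csv <- paste0(prefix, "_collated.csv")
  d <- fit$collated
  utils::write.csv(data.frame(label = d$label, mean_logZ = d$mean_logZ,
                              sem_logZ = d$sem_logZ,
                              mean_per_step_time = d$mean_per_step_time,
                              n_runs = d$n_successful_runs),
                   csv, row.names = FALSE)
  js <- paste0(prefix, "_selection.json")
  s <- fit$selection
  jsonlite::write_json(list(optimal = s$optimal,
                            evidence_ranking = s$evidence_ranking,
                            efficient_set = s$efficient_set,
                            rationale = as.list(s$rationale),
                            time_fold = s$time_fold,
                            sem_mult = s$sem_mult),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
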