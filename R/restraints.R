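## restraints module: the repartitioned scoring system.
##
## The posterior over a representation factors as prior x likelihood.  A flat
## stereochemistry prior is a poor starting distribution for nested sampling
## when the crosslink likelihood is concentrated, so the posterior is
## repartitioned: a random subset of the crosslinks (default 30%) joins the
## stereochemistry restraints to form a "modified prior" used for Monte Carlo
## sampling, and the remaining crosslinks form the likelihood whose evidence
## is integrated.  The product of the two factors -- the posterior -- is
## unchanged by the split.

#' Read a crosslink table
#'
#' CSV with header `protein1,residue1,protein2,residue2`, the common
#' crosslinking-MS restraint table dialect.  Self links (identical residue on
#' both sides) are rejected; duplicates are kept unless `dedup = TRUE`
#' (real datasets are redundant).
#'
#' @param file path to the CSV.
#' @param dedup drop duplicated records?
#' @return data frame with the four columns above.
#' @export
read_crosslinks <- function(file, dedup = FALSE) {
  xl <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(protein1 = "character",
                                       protein2 = "character"))
  need <- c("protein1", "residue1", "protein2", "residue2")
  if (!all(need %in% names(xl)))
    stop("crosslink file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  xl <- xl[need]
  self <- xl$protein1 == xl$protein2 & xl$residue1 == xl$residue2
  if (any(self))
    stop("self-crosslink (same residue on both sides) at row ",
         which(self)[1], call. = FALSE)
  if (dedup) xl <- unique(xl)
  rownames(xl) <- NULL
  xl
}

#' Write a crosslink table
#'
#' @param crosslinks data frame as returned by [read_crosslinks()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_crosslinks <- function(crosslinks, file) {
  cols <- c("protein1", "residue1", "protein2", "residue2")
  utils::write.csv(crosslinks[cols], file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Randomly split crosslinks into prior and likelihood sets
#'
#' Draws `round(prior_fraction * N)` crosslinks uniformly at random into the
#' prior set (they will be scored inside the modified prior); the rest form
#' the likelihood set.  The same seed always yields the same split; the
#' caller's RNG stream is left untouched.
#'
#' @param crosslinks crosslink data frame.
#' @param prior_fraction fraction of crosslinks moved into the modified
#'   prior, in `[0, 1]`; default 0.3.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list with elements `prior` and `likelihood` (disjoint data frames
#'   whose union is the input).
#' @export
repartition_restraints <- function(crosslinks, prior_fraction = 0.3,
                                   seed = NULL) {
  if (prior_fraction < 0 || prior_fraction > 1)
    stop("'prior_fraction' must be in [0, 1]", call. = FALSE)
  n <- nrow(crosslinks)
  if (n == 0) {
    if (prior_fraction > 0)
      warning("no crosslinks to repartition; both sets empty")
    return(list(prior = crosslinks, likelihood = crosslinks))
  }
  n_prior <- round(prior_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_prior))
  prior <- crosslinks[sort(idx), , drop = FALSE]
  likelihood <- crosslinks[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(prior) <- rownames(likelihood) <- NULL
  list(prior = prior, likelihood = likelihood)
}

#' Assemble the repartitioned scoring configuration
#'
#' Bundles the prior/likelihood crosslink sets with the restraint parameters:
#' the crosslink score per link is `omega + (1 - omega) / (1 + exp((d - d0) /
#' slope))` on the center-to-center bead distance `d`, a sigmoid that is ~1
#' for satisfied links and decays to the false-positive floor `omega` beyond
#' the cutoff; excluded volume and chain connectivity are one-sided harmonic
#' penalties with force constants `k_ev` and `k_conn`.
#'
#' @param prior_crosslinks,likelihood_crosslinks disjoint crosslink data
#'   frames (see [repartition_restraints()]); either may be empty or `NULL`.
#' @param d0 crosslink cutoff distance (A), sigmoid midpoint.
#' @param slope sigmoid width (A).
#' @param omega false-positive floor probability in `[0, 1)`; keeps the
#'   log-likelihood bounded below, which plateau detection requires.
#' @param k_ev,k_conn force constants (1/A^2); 0 disables the term.
#' @return an object of class `"restraint_config"`.
#' @export
restraint_config <- function(prior_crosslinks = NULL,
                             likelihood_crosslinks = NULL,
                             d0 = 21, slope = 2, omega = 0.01,
                             k_ev = 1, k_conn = 1) {
  empty <- data.frame(protein1 = character(), residue1 = integer(),
                      protein2 = character(), residue2 = integer())
  prior_crosslinks <- if (is.null(prior_crosslinks)) empty
                      else as.data.frame(prior_crosslinks)
  likelihood_crosslinks <- if (is.null(likelihood_crosslinks)) empty
                           else as.data.frame(likelihood_crosslinks)
  d0 <- check_number(d0, "d0", 0, strict = TRUE)
  slope <- check_number(slope, "slope", 0, strict = TRUE)
  omega <- check_number(omega, "omega", 0)
  if (omega >= 1) stop("'omega' must be < 1", call. = FALSE)
  k_ev <- check_number(k_ev, "k_ev", 0)
  k_conn <- check_number(k_conn, "k_conn", 0)
  structure(list(prior_crosslinks = prior_crosslinks,
                 likelihood_crosslinks = likelihood_crosslinks,
                 d0 = d0, slope = slope, omega = omega,
                 k_ev = k_ev, k_conn = k_conn),
            class = "restraint_config")
}

#' @export
print.restraint_config <- function(x, ...) {
  cat(sprintf(paste0("Restraint configuration: %d prior + %d likelihood ",
                     "crosslinks\n  d0 = %g A, slope = %g A, omega = %g; ",
                     "k_ev = %g, k_conn = %g\n"),
              nrow(x$prior_crosslinks), nrow(x$likelihood_crosslinks),
              x$d0, x$slope, x$omega, x$k_ev, x$k_conn))
  invisible(x)
}

## vectorized crosslink log-probability on precomputed bead index pairs
xl_loglik_pairs <- function(coords, i, j, d0, slope, omega) {
  if (!length(i)) return(0)
  dx <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  d <- sqrt(rowSums(dx * dx))
  sum(log(omega + (1 - omega) / (1 + exp((d - d0) / slope))))
}

#' Crosslink log-likelihood of a structural model
#'
#' Sum over crosslinks of `log p(d)` with
#' `p(d) = omega + (1 - omega) / (1 + exp((d - d0) / slope))`, where `d` is
#' the center-to-center distance of the beads containing the two crosslinked
#' residues.  Each term lies in `(log omega, 0)`.
#'
#' @param model a [structure_model()].
#' @param crosslinks crosslink data frame.
#' @param d0,slope,omega sigmoid parameters (see [restraint_config()]).
#' @return total log-probability (0 for an empty table).
#' @export
crosslink_loglik <- function(model, crosslinks, d0 = 21, slope = 2,
                             omega = 0.01) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(crosslinks) || nrow(crosslinks) == 0) return(0)
  topo <- model$topology
  what <- sprintf("crosslink %s:%s--%s:%s", crosslinks$protein1,
                  crosslinks$residue1, crosslinks$protein2,
                  crosslinks$residue2)
  i <- mapply(function(p, r, w) residue_to_bead(topo, p, r, w),
              crosslinks$protein1, crosslinks$residue1, what)
  j <- mapply(function(p, r, w) residue_to_bead(topo, p, r, w),
              crosslinks$protein2, crosslinks$residue2, what)
  xl_loglik_pairs(model$coordinates, as.integer(i), as.integer(j),
                  d0, slope, omega)
}

## internal excluded-volume / connectivity cores working on raw coordinates
ev_penalty <- function(coords, topo, k_ev) {
  if (k_ev == 0 || !length(topo$ev$keep)) return(0)
  d <- stats::dist(coords)
  ov <- topo$ev$rsum - d[topo$ev$keep]
  ov <- ov[ov > 0]
  if (!length(ov)) return(0)
  -(k_ev / 2) * sum(ov * ov)
}

conn_penalty <- function(coords, topo, k_conn) {
  if (k_conn == 0 || !length(topo$conn$i)) return(0)
  dx <- coords[topo$conn$i, , drop = FALSE] - coords[topo$conn$j, , drop = FALSE]
  stretch <- sqrt(rowSums(dx * dx)) - topo$conn$rest
  stretch <- stretch[stretch > 0]
  if (!length(stretch)) return(0)
  -(k_conn / 2) * sum(stretch * stretch)
}

#' Excluded-volume log-prior (unnormalized)
#'
#' `-(k_ev / 2) * sum over bead pairs of max(0, r_i + r_j - d_ij)^2`, pairs
#' within one rigid body exempt (their overlap is fixed by construction).
#' Zero when no beads interpenetrate; never positive.
#'
#' @param model a [structure_model()].
#' @param k_ev force constant (1/A^2).
#' @return log-prior contribution, `<= 0`.
#' @export
excluded_volume_logprior <- function(model, k_ev = 1) {
  stopifnot(inherits(model, "structure_model"))
  ev_penalty(model$coordinates, model$topology, check_number(k_ev, "k_ev", 0))
}

#' Chain-connectivity log-prior (unnormalized)
#'
#' For each pair of beads consecutive along a chain,
#' `-(k_conn / 2) * max(0, d_ij - (r_i + r_j))^2`: consecutive beads may
#' touch or overlap freely but pay a one-sided harmonic penalty for gaps.
#'
#' @param model a [structure_model()].
#' @param k_conn force constant (1/A^2).
#' @return log-prior contribution, `<= 0`.
#' @export
connectivity_logprior <- function(model, k_conn = 1) {
  stopifnot(inherits(model, "structure_model"))
  conn_penalty(model$coordinates, model$topology,
               check_number(k_conn, "k_conn", 0))
}

#' Score a model under the repartitioned posterior
#'
#' @param model a [structure_model()].
#' @param config a [restraint_config()].
#' @return list with `log_modified_prior` (stereochemistry + prior-set
#'   crosslinks) and `log_likelihood` (likelihood-set crosslinks).  Their sum
#'   is the unpartitioned posterior log-score and is invariant to how the
#'   crosslinks were split.
#' @export
score_model <- function(model, config) {
  stopifnot(inherits(config, "restraint_config"))
  lp <- excluded_volume_logprior(model, config$k_ev) +
    connectivity_logprior(model, config$k_conn) +
    crosslink_loglik(model, config$prior_crosslinks,
                     config$d0, config$slope, config$omega)
  ll <- crosslink_loglik(model, config$likelihood_crosslinks,
                         config$d0, config$slope, config$omega)
  list(log_modified_prior = lp, log_likelihood = ll)
}
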