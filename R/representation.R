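## assembly_model module: coarse-grained bead representations of an assembly.
##
## A candidate representation maps each chain to a string of spherical beads,
## each bead covering `residues_per_bead` contiguous residues (the last bead
## of a chain covers the remainder).  Beads belonging to chains that share a
## rigid-body label move as one rigid unit (6 degrees of freedom); all other
## beads are flexible (3 degrees of freedom each).

#' Volume-equivalent bead radius
#'
#' Radius of a sphere whose volume equals `n_residues` times the mean
#' amino-acid volume (130 A^3): `(3 n V / 4 pi)^(1/3)`.  Used for excluded
#' volume and chain connectivity rest lengths.
#'
#' @param n_residues integer vector, residues per bead (>= 1).
#' @param residue_volume mean residue volume in A^3.
#' @return bead radius (or radii) in Angstrom.
#' @export
#' @examples
#' bead_radius(1)          # ~3.14 A
#' bead_radius(8) / bead_radius(1)  # exactly 2 (cube-root homogeneity)
bead_radius <- function(n_residues, residue_volume = 130) {
  if (!length(n_residues) || !is.numeric(n_residues) ||
      any(!is.finite(n_residues)) || any(n_residues < 1))
    stop("'n_residues' must be >= 1", call. = FALSE)
  (3 * n_residues * residue_volume / (4 * pi))^(1 / 3)
}

#' Build a coarse-grained bead representation
#'
#' Divides every chain into consecutive blocks of `residues_per_bead`
#' residues (1-based, inclusive ranges); the final bead of a chain holds the
#' remainder.  Chains carrying the same non-missing `rigid_body` label
#' contribute their beads to one rigid body.
#'
#' @param chains data frame with columns `chain_id` (unique), `length`
#'   (residue count >= 1) and optionally `rigid_body` (NA or "" = flexible),
#'   as read by [read_topology()].
#' @param residues_per_bead integer >= 1; the resolution of the candidate
#'   representation.
#' @return an object of class `"bead_topology"`: a list with a `beads` data
#'   frame (`chain_id`, `residue_start`, `residue_end`, `n_res`, `radius`,
#'   `rigid_body`, `flexible`), the `rigid_bodies` mapping (label -> bead
#'   indices), and precomputed connectivity/excluded-volume bookkeeping.
#' @export
#' @examples
#' ch <- data.frame(chain_id = "A", length = 100)
#' build_representation(ch, 20)  # 5 beads of 20 residues
build_representation <- function(chains, residues_per_bead) {
  residues_per_bead <- check_count(residues_per_bead, "residues_per_bead")
  chains <- as.data.frame(chains)
  if (!all(c("chain_id", "length") %in% names(chains)))
    stop("'chains' needs columns 'chain_id' and 'length'", call. = FALSE)
  if (anyDuplicated(chains$chain_id))
    stop("duplicate chain_id in topology: ",
         paste(unique(chains$chain_id[duplicated(chains$chain_id)]),
               collapse = ", "), call. = FALSE)
  if (any(chains$length < 1) || any(chains$length != round(chains$length)))
    stop("chain lengths must be integers >= 1", call. = FALSE)
  rb <- if ("rigid_body" %in% names(chains)) as.character(chains$rigid_body)
        else rep(NA_character_, nrow(chains))
  rb[!is.na(rb) & !nzchar(rb)] <- NA_character_

  bead_list <- lapply(seq_len(nrow(chains)), function(k) {
    len <- as.integer(chains$length[k])
    start <- seq.int(1L, len, by = residues_per_bead)
    end <- pmin(start + residues_per_bead - 1L, len)
    data.frame(chain_id = as.character(chains$chain_id[k]),
               residue_start = start, residue_end = end,
               n_res = end - start + 1L,
               rigid_body = rb[k],
               stringsAsFactors = FALSE)
  })
  beads <- do.call(rbind, bead_list)
  beads$radius <- bead_radius(beads$n_res)
  beads$flexible <- is.na(beads$rigid_body)
  beads <- beads[c("chain_id", "residue_start", "residue_end", "n_res",
                   "radius", "rigid_body", "flexible")]
  n <- nrow(beads)

  rigid_bodies <- split(seq_len(n), beads$rigid_body)

  ## per-chain bookkeeping for residue -> bead lookups
  n_per_chain <- vapply(bead_list, nrow, 0L)
  first_bead <- stats::setNames(cumsum(c(0L, n_per_chain[-length(n_per_chain)])) + 1L,
                                as.character(chains$chain_id))
  chain_len <- stats::setNames(as.integer(chains$length),
                               as.character(chains$chain_id))
  chain_n_beads <- stats::setNames(n_per_chain, as.character(chains$chain_id))

  ## consecutive-bead pairs along each chain (connectivity restraints)
  conn_i <- integer(0); conn_j <- integer(0)
  off <- 0L
  for (nb in n_per_chain) {
    if (nb > 1) {
      conn_i <- c(conn_i, off + seq_len(nb - 1L))
      conn_j <- c(conn_j, off + seq_len(nb - 1L) + 1L)
    }
    off <- off + nb
  }
  conn_rest <- beads$radius[conn_i] + beads$radius[conn_j]

  ## excluded-volume pair bookkeeping in stats::dist ordering
  ## (lower triangle, column-major); pairs within one rigid body are exempt
  if (n > 1) {
    rsum <- outer(beads$radius, beads$radius, "+")
    lab <- beads$rigid_body
    same_rb <- outer(lab, lab, function(a, b) !is.na(a) & !is.na(b) & a == b)
    lt <- lower.tri(rsum)
    ev_keep <- which(!same_rb[lt])
    ev_rsum <- rsum[lt][ev_keep]
  } else {
    ev_keep <- integer(0)
    ev_rsum <- numeric(0)
  }

  structure(list(beads = beads,
                 residues_per_bead = residues_per_bead,
                 rigid_bodies = rigid_bodies,
                 chains = chains,
                 n_beads = n,
                 first_bead = first_bead,
                 chain_len = chain_len,
                 chain_n_beads = chain_n_beads,
                 conn = list(i = conn_i, j = conn_j, rest = conn_rest),
                 ev = list(keep = ev_keep, rsum = ev_rsum)),
            class = "bead_topology")
}

#' @export
print.bead_topology <- function(x, ...) {
  cat(sprintf("Bead representation: %d bead(s), %d residue(s)/bead\n",
              x$n_beads, x$residues_per_bead))
  cat(sprintf("  chains: %s\n",
              paste(sprintf("%s (%d aa)", x$chains$chain_id, x$chains$length),
                    collapse = ", ")))
  cat(sprintf("  rigid bodies: %d; flexible beads: %d; free parameters: %d\n",
              length(x$rigid_bodies), sum(x$beads$flexible),
              count_free_parameters(x)))
  invisible(x)
}

#' Count free parameters of a representation
#'
#' `3 n + 6 m`, where `n` is the number of flexible beads (three translational
#' degrees of freedom each) and `m` the number of rigid bodies (six each).
#' Useful for choosing the number of live points, which should be at least
#' the number of free parameters.
#'
#' @param topology a [build_representation()] result.
#' @return integer parameter count.
#' @export
count_free_parameters <- function(topology) {
  stopifnot(inherits(topology, "bead_topology"))
  3L * sum(topology$beads$flexible) + 6L * length(topology$rigid_bodies)
}

#' Instantiate a structural model
#'
#' A structural model is one configuration of a representation: a 3-D
#' coordinate (Angstrom) for every bead center.
#'
#' @param coordinates numeric matrix, one row per bead, columns x/y/z.
#' @param topology the [build_representation()] the coordinates instantiate.
#' @return an object of class `"structure_model"`.
#' @export
structure_model <- function(coordinates, topology) {
  stopifnot(inherits(topology, "bead_topology"))
  coordinates <- as.matrix(coordinates)
  if (is.null(dim(coordinates)) || ncol(coordinates) != 3 ||
      nrow(coordinates) != topology$n_beads)
    stop("'coordinates' must be an n_beads x 3 matrix", call. = FALSE)
  if (!all(is.finite(coordinates)))
    stop("coordinates must be finite", call. = FALSE)
  storage.mode(coordinates) <- "double"
  new_structure_model(coordinates, topology)
}

## fast internal constructor (no validation) for the sampler hot path
new_structure_model <- function(coordinates, topology) {
  structure(list(coordinates = coordinates, topology = topology),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structural model: %d beads (%d residues/bead)\n",
              x$topology$n_beads, x$topology$residues_per_bead))
  invisible(x)
}

## map (chain, residue) pairs to global bead indices; `what` names the
## offending record in error messages (e.g. a crosslink)
residue_to_bead <- function(topology, chain_id, residue, what = "record") {
  chain_id <- as.character(chain_id)
  bad_chain <- !(chain_id %in% names(topology$chain_len))
  if (any(bad_chain))
    stop(sprintf("%s refers to unknown chain '%s'", what,
                 chain_id[which(bad_chain)[1]]), call. = FALSE)
  len <- topology$chain_len[chain_id]
  bad_res <- residue < 1 | residue > len | residue != round(residue)
  if (any(bad_res)) {
    k <- which(bad_res)[1]
    stop(sprintf("%s: residue %s outside chain '%s' (length %d)",
                 what, residue[k], chain_id[k], len[k]), call. = FALSE)
  }
  local_bead <- ceiling(residue / topology$residues_per_bead)
  ## residues never index past the remainder bead, but guard anyway
  local_bead <- pmin(local_bead, topology$chain_n_beads[chain_id])
  as.integer(topology$first_bead[chain_id] + local_bead - 1L)
}

#' Read an assembly topology table
#'
#' Tab-separated, one row per chain, columns `chain_id`, `length`,
#' `rigid_body` (empty = flexible chain).
#'
#' @param file path to the TSV.
#' @return data frame suitable for [build_representation()].
#' @export
read_topology <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"),
                           colClasses = c(chain_id = "character"))
  if (!all(c("chain_id", "length") %in% names(tab)))
    stop("topology file needs columns 'chain_id' and 'length'", call. = FALSE)
  if (!"rigid_body" %in% names(tab)) tab$rigid_body <- NA_character_
  tab
}

#' Write an assembly topology table
#'
#' @param chains chain data frame (see [read_topology()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_topology <- function(chains, file) {
  out <- data.frame(chain_id = chains$chain_id, length = chains$length,
                    rigid_body = if ("rigid_body" %in% names(chains))
                      chains$rigid_body else NA_character_)
  out$rigid_body[is.na(out$rigid_body)] <- ""
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a bead model as a pseudo-atom PDB
#'
#' One HETATM carbon pseudo-atom per bead: the chain field holds the first
#' character of the chain id, the residue number is the bead's first residue,
#' occupancy is 1.00 and the B-factor column carries the bead radius.
#'
#' @param model a [structure_model()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bead_pdb <- function(model, file) {
  stopifnot(inherits(model, "structure_model"))
  b <- model$topology$beads
  xyz <- model$coordinates
  lines <- sprintf(
    "HETATM%5d  C   BEA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(b)), substr(b$chain_id, 1, 1), b$residue_start %% 10000L,
    xyz[, 1], xyz[, 2], xyz[, 3], 1.00, b$radius)
  writeLines(c(lines, "END"), file)
  invisible(file)
}
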