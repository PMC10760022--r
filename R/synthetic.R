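## synthetic_data module: reference assemblies and simulated crosslinks.
##
## Stands in for real benchmark complexes so every stage of the pipeline can
## be exercised without downloads: a compact multi-chain "true" structure is
## generated at residue resolution, and crosslinks are simulated from it with
## a distance cutoff and a false-positive fraction, mimicking the statistical
## structure of crosslinking-MS datasets.

#' Generate a synthetic reference assembly
#'
#' Each chain is a fixed-bond-length (3.8 A) random walk with soft
#' self-avoidance (placements closer than 3 A to an existing residue are
#' resampled a bounded number of times), confined to a sphere sized so the
#' assembly's radius of gyration is about
#' `compactness * N_res^(1/3) * 3 A` -- the scaling of a compact globule.
#' Chains start at random positions in the interior.  Fully deterministic
#' given `seed`.
#'
#' @param chains chain table with `chain_id` and `length` columns.
#' @param compactness target radius-of-gyration scale factor.
#' @param seed integer seed.
#' @return an object of class `"reference_structure"`: a named list of
#'   per-chain residue coordinate matrices plus the chain table.
#' @export
generate_reference_assembly <- function(chains, compactness = 1, seed = 1) {
  chains <- as.data.frame(chains)
  if (nrow(chains) < 1) stop("need at least one chain", call. = FALSE)
  compactness <- check_number(compactness, "compactness", 0, strict = TRUE)
  bond <- 3.8
  min_sep <- 3.0
  n_tot <- sum(chains$length)
  rg_target <- compactness * n_tot^(1 / 3) * 3
  confine <- rg_target * sqrt(5 / 3)  # Rg of a uniform ball of radius R is R*sqrt(3/5)

  coords <- with_seed(seed, {
    placed <- matrix(numeric(0), 0, 3)
    out <- vector("list", nrow(chains))
    for (k in seq_len(nrow(chains))) {
      len <- as.integer(chains$length[k])
      xyz <- matrix(0, len, 3)
      repeat {
        p0 <- stats::runif(3, -confine / 2, confine / 2)
        if (sum(p0^2) <= (confine / 2)^2) break
      }
      xyz[1, ] <- p0
      if (len > 1) for (r in 2:len) {
        best <- NULL
        for (try in 1:30) {
          p <- xyz[r - 1, ] + bond * random_unit_vector()
          if (sum(p^2) > confine^2) next
          clash <- FALSE
          if (nrow(placed) > 0) {
            d2 <- rowSums(sweep(placed, 2, p)^2)
            clash <- any(d2 < min_sep^2)
          }
          if (!clash && r > 2) {
            d2o <- rowSums(sweep(xyz[1:(r - 2), , drop = FALSE], 2, p)^2)
            clash <- any(d2o < min_sep^2)
          }
          best <- p
          if (!clash) break
        }
        if (is.null(best))  # sphere wall everywhere: step inward
          best <- xyz[r - 1, ] - bond * xyz[r - 1, ] / sqrt(sum(xyz[r - 1, ]^2))
        xyz[r, ] <- best
      }
      out[[k]] <- xyz
      placed <- rbind(placed, xyz)
    }
    names(out) <- as.character(chains$chain_id)
    out
  })

  structure(list(coordinates = coords, chains = chains,
                 compactness = compactness, seed = seed),
            class = "reference_structure")
}

#' @export
print.reference_structure <- function(x, ...) {
  n <- sum(vapply(x$coordinates, nrow, 0L))
  all_xyz <- do.call(rbind, x$coordinates)
  rg <- sqrt(mean(rowSums(sweep(all_xyz, 2, colMeans(all_xyz))^2)))
  cat(sprintf("Synthetic reference assembly: %d chains, %d residues, Rg = %.1f A\n",
              length(x$coordinates), n, rg))
  invisible(x)
}

## flat residue index table for a reference structure
ref_residue_table <- function(ref) {
  do.call(rbind, lapply(names(ref$coordinates), function(ch)
    data.frame(chain_id = ch,
               residue = seq_len(nrow(ref$coordinates[[ch]])))))
}

#' Simulate a crosslink dataset from a reference structure
#'
#' Each record is, with probability `1 - fp_rate`, a uniformly chosen residue
#' pair whose distance in the reference is at most `cutoff` (a true
#' positive), and otherwise a uniformly chosen random residue pair (a false
#' positive).  Duplicates may occur, as in real datasets.  The true-positive
#' flags are attached as `attr(, "truth")` for testing only; they are not
#' written by [write_crosslinks()].
#'
#' @param ref a [generate_reference_assembly()] result.
#' @param n number of crosslink records.
#' @param cutoff crosslinker span on residue centers (A).
#' @param fp_rate false-positive fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return crosslink data frame (`protein1,residue1,protein2,residue2`).
#' @export
simulate_crosslinks <- function(ref, n, cutoff = 25, fp_rate = 0.1,
                                seed = 1) {
  stopifnot(inherits(ref, "reference_structure"))
  n <- check_count(n, "n")
  if (fp_rate < 0 || fp_rate > 1)
    stop("'fp_rate' must be in [0, 1]", call. = FALSE)
  tab <- ref_residue_table(ref)
  xyz <- do.call(rbind, ref$coordinates)
  d <- as.matrix(stats::dist(xyz))
  within <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(within) == 0)
    stop("no residue pair within the crosslink cutoff", call. = FALSE)
  n_res <- nrow(tab)

  with_seed(seed, {
    is_fp <- stats::runif(n) < fp_rate
    pick_true <- sample.int(nrow(within), n, replace = TRUE)
    i <- within[pick_true, 1]
    j <- within[pick_true, 2]
    if (any(is_fp)) {
      nf <- sum(is_fp)
      fi <- sample.int(n_res, nf, replace = TRUE)
      fj <- sample.int(n_res, nf, replace = TRUE)
      ## redraw collisions so a record never links a residue to itself
      while (any(fi == fj)) {
        hit <- fi == fj
        fj[hit] <- sample.int(n_res, sum(hit), replace = TRUE)
      }
      i[is_fp] <- fi
      j[is_fp] <- fj
    }
    out <- data.frame(protein1 = tab$chain_id[i], residue1 = tab$residue[i],
                      protein2 = tab$chain_id[j], residue2 = tab$residue[j],
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- !is_fp
    out
  })
}

#' Write reference coordinates as a pseudo-atom PDB
#'
#' One CA-like HETATM pseudo-atom per residue.
#'
#' @param ref a [generate_reference_assembly()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_reference_pdb <- function(ref, file) {
  stopifnot(inherits(ref, "reference_structure"))
  lines <- character(0)
  serial <- 0L
  for (ch in names(ref$coordinates)) {
    xyz <- ref$coordinates[[ch]]
    for (r in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  CA  RES %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial %% 100000L, substr(ch, 1, 1), r %% 10000L,
        xyz[r, 1], xyz[r, 2], xyz[r, 3], 1.00, 0.00))
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
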