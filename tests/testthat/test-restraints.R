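# shared fixture: a two-chain topology at single-residue resolution so bead
# positions can be pinned exactly
line_model <- function(distances, length = NULL) {
  # beads of one chain laid along the x axis with given consecutive gaps
  n <- length %||% (length(distances) + 1)
  topo <- build_representation(data.frame(chain_id = "A", length = n), 1)
  x <- cumsum(c(0, distances))
  structure_model(cbind(x, 0, 0), topo)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("repartitioning draws the right fraction, disjointly, by seed", {
  xl <- data.frame(protein1 = "A", residue1 = 1:10,
                   protein2 = "B", residue2 = 11:20)
  sp <- repartition_restraints(xl, 0.3, seed = 7)
  expect_equal(nrow(sp$prior), 3)
  expect_equal(nrow(sp$likelihood), 7)
  merged <- rbind(sp$prior, sp$likelihood)
  expect_equal(merged[order(merged$residue1), ], xl, ignore_attr = TRUE)

  again <- repartition_restraints(xl, 0.3, seed = 7)
  expect_identical(sp, again)

  none <- repartition_restraints(xl, 0)
  expect_equal(nrow(none$prior), 0)
  expect_equal(nrow(none$likelihood), 10)
  all_prior <- repartition_restraints(xl, 1)
  expect_equal(nrow(all_prior$prior), 10)

  empty <- xl[0, ]
  expect_warning(sp0 <- repartition_restraints(empty, 0.3), "empty")
  expect_equal(nrow(sp0$prior), 0)
  expect_equal(nrow(sp0$likelihood), 0)
})

test_that("crosslink scores are sigmoid with a false-positive floor", {
  d0 <- 21; omega <- 0.01
  m <- line_model(d0)  # two beads exactly at the midpoint distance
  xl <- data.frame(protein1 = "A", residue1 = 1, protein2 = "A", residue2 = 2)
  expect_equal(crosslink_loglik(m, xl, d0 = d0, omega = omega),
               log(omega + (1 - omega) / 2), tolerance = 1e-12)
  expect_equal(log(0.505), crosslink_loglik(m, xl, d0 = d0, omega = omega),
               tolerance = 1e-9)

  far <- line_model(5000)
  expect_equal(crosslink_loglik(far, xl, omega = omega), log(omega),
               tolerance = 1e-9)

  # log-additivity over records
  two <- rbind(xl, xl)
  expect_equal(crosslink_loglik(m, two), 2 * crosslink_loglik(m, xl),
               tolerance = 1e-12)

  # monotone non-increasing in distance
  lls <- vapply(seq(1, 60, by = 1), function(d)
    crosslink_loglik(line_model(d), xl), 0)
  expect_true(all(diff(lls) <= 0))
  expect_true(all(lls > log(omega) & lls < 0))
})

test_that("excluded volume penalizes only interpenetration", {
  topo <- build_representation(data.frame(chain_id = c("A", "B"),
                                          length = c(1, 1)), 1)
  rsum <- sum(topo$beads$radius)
  apart <- structure_model(rbind(c(0, 0, 0), c(rsum + 5, 0, 0)), topo)
  expect_equal(excluded_volume_logprior(apart, 1), 0)

  overlap1 <- structure_model(rbind(c(0, 0, 0), c(rsum - 1, 0, 0)), topo)
  expect_equal(excluded_volume_logprior(overlap1, 1), -0.5, tolerance = 1e-12)
  expect_equal(excluded_volume_logprior(overlap1, 4), -2, tolerance = 1e-12)

  # beads sharing a rigid body are exempt
  rigid <- build_representation(data.frame(chain_id = c("A", "B"),
                                           length = c(1, 1),
                                           rigid_body = c("r", "r")), 1)
  clash <- structure_model(rbind(c(0, 0, 0), c(0.1, 0, 0)), rigid)
  expect_equal(excluded_volume_logprior(clash, 1), 0)
})

test_that("connectivity penalizes only stretched bonds", {
  topo <- build_representation(data.frame(chain_id = "A", length = 2), 1)
  rsum <- sum(topo$beads$radius)
  touching <- structure_model(rbind(c(0, 0, 0), c(rsum, 0, 0)), topo)
  expect_equal(connectivity_logprior(touching, 1), 0)

  stretched <- structure_model(rbind(c(0, 0, 0), c(rsum + 1, 0, 0)), topo)
  expect_equal(connectivity_logprior(stretched, 1), -0.5, tolerance = 1e-12)

  compressed <- structure_model(rbind(c(0, 0, 0), c(rsum / 2, 0, 0)), topo)
  expect_equal(connectivity_logprior(compressed, 1), 0)

  single <- build_representation(data.frame(chain_id = "A", length = 1), 1)
  one <- structure_model(matrix(0, 1, 3), single)
  expect_equal(connectivity_logprior(one, 1), 0)
})

test_that("all score terms are invariant under rigid transformation", {
  set.seed(31)
  chains <- data.frame(chain_id = c("A", "B"), length = c(20, 15))
  topo <- build_representation(chains, 5)
  ref <- generate_reference_assembly(chains, seed = 8)
  xl <- simulate_crosslinks(ref, 10, seed = 9)
  sp <- repartition_restraints(xl, 0.3, seed = 10)
  config <- restraint_config(sp$prior, sp$likelihood)

  m <- random_model(topo)
  rot <- nsrep:::rotation_matrix(c(1, 2, 3), 0.77)
  shifted <- structure_model(m$coordinates %*% t(rot) +
                               matrix(c(12, -8, 101), topo$n_beads, 3,
                                      byrow = TRUE), topo)
  s1 <- score_model(m, config)
  s2 <- score_model(shifted, config)
  expect_equal(s1$log_modified_prior, s2$log_modified_prior,
               tolerance = 1e-9)
  expect_equal(s1$log_likelihood, s2$log_likelihood, tolerance = 1e-9)
})

test_that("the posterior score is invariant to the prior/likelihood split", {
  set.seed(12)
  chains <- data.frame(chain_id = c("A", "B"), length = c(22, 18))
  topo <- build_representation(chains, 4)
  ref <- generate_reference_assembly(chains, seed = 13)
  xl <- simulate_crosslinks(ref, 14, seed = 14)
  m <- random_model(topo)

  baseline <- restraint_config(likelihood_crosslinks = xl)
  total <- sum(unlist(score_model(m, baseline)))
  for (f in c(0, 0.25, 0.5, 1)) {
    sp <- repartition_restraints(xl, f, seed = 99)
    s <- score_model(m, restraint_config(sp$prior, sp$likelihood))
    expect_equal(s$log_modified_prior + s$log_likelihood, total,
                 tolerance = 1e-9)
  }

  # all crosslinks in the prior: the likelihood is an empty sum
  all_prior <- restraint_config(prior_crosslinks = xl)
  expect_equal(score_model(m, all_prior)$log_likelihood, 0)
})

test_that("a relaxed, connected, crosslink-free model scores (0, 0)", {
  topo <- build_representation(data.frame(chain_id = "A", length = 9), 3)
  r <- topo$beads$radius
  gaps <- r[-length(r)] + r[-1]
  m <- structure_model(cbind(cumsum(c(0, gaps)), 0, 0), topo)
  s <- score_model(m, restraint_config())
  expect_equal(s$log_modified_prior, 0)
  expect_equal(s$log_likelihood, 0)
})

test_that("mapping errors name the offending crosslink", {
  topo <- build_representation(data.frame(chain_id = "A", length = 10), 5)
  m <- structure_model(matrix(rnorm(6), 2, 3), topo)
  bad_res <- data.frame(protein1 = "A", residue1 = 99,
                        protein2 = "A", residue2 = 2)
  expect_error(crosslink_loglik(m, bad_res), "A:99")
  bad_chain <- data.frame(protein1 = "Z", residue1 = 1,
                          protein2 = "A", residue2 = 2)
  expect_error(crosslink_loglik(m, bad_chain), "Z")
})

test_that("crosslink tables round-trip and reject self links", {
  xl <- data.frame(protein1 = c("A", "B"), residue1 = c(3, 7),
                   protein2 = c("B", "A"), residue2 = c(9, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_crosslinks(xl, f)
  expect_equal(read_crosslinks(f), xl, ignore_attr = TRUE)

  self <- data.frame(protein1 = "A", residue1 = 3,
                     protein2 = "A", residue2 = 3)
  write_crosslinks(self, f)
  expect_error(read_crosslinks(f), "self")

  dup <- rbind(xl, xl[1, ])
  write_crosslinks(dup, f)
  expect_equal(nrow(read_crosslinks(f)), 3)
  expect_equal(nrow(read_crosslinks(f, dedup = TRUE)), 2)
})
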