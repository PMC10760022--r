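fake_run <- function(logz, t = 1e-4) {
  structure(list(log_evidence = logz, per_step_time = t), class = "ns_result")
}

test_that("collation reports mean, standard error and timing", {
  runs <- lapply(c(-10, -11, -12), fake_run)
  col <- collate_runs(runs, "20")
  expect_equal(col$mean_logZ, -11)
  expect_equal(col$sem_logZ, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(col$n_successful_runs, 3)

  expect_warning(single <- collate_runs(list(fake_run(-5)), "x"), "single")
  expect_equal(single$sem_logZ, 0)

  failed <- collate_runs(list(), "y")
  expect_true(failed$failed)
  expect_equal(failed$n_successful_runs, 0)
})

test_that("log Bayes factors are antisymmetric and additive", {
  a <- data.frame(mean_logZ = -100)
  b <- data.frame(mean_logZ = -103)
  c <- data.frame(mean_logZ = -110)
  expect_equal(log_bayes_factor(a, a), 0)
  expect_equal(log_bayes_factor(a, b), 3)
  expect_equal(log_bayes_factor(a, b), -log_bayes_factor(b, a))
  expect_equal(log_bayes_factor(a, c),
               log_bayes_factor(a, b) + log_bayes_factor(b, c))
})

ranked_input <- function(...) {
  rows <- list(...)
  data.frame(label = vapply(rows, `[[`, "", 1),
             mean_logZ = vapply(rows, function(r) r[[2]], 0),
             sem_logZ = vapply(rows, function(r) r[[3]], 0),
             mean_per_step_time = vapply(rows, function(r) r[[4]], 0),
             n_successful_runs = 3L, failed = FALSE)
}

test_that("selection filters on time first, then on evidence overlap", {
  # identical candidates are all optimal
  same <- ranked_input(list("a", -50, 1, 1), list("b", -50, 1, 1),
                       list("c", -50, 1, 1))
  expect_setequal(rank_representations(same)$optimal, c("a", "b", "c"))

  # overlapping evidence intervals within the efficient set
  pair <- ranked_input(list("A", -50, 2, 1), list("B", -51, 2, 2))
  rep <- rank_representations(pair)
  expect_setequal(rep$optimal, c("A", "B"))
  expect_setequal(rep$efficient_set, c("A", "B"))

  # disjoint intervals exclude the weaker candidate
  gap <- ranked_input(list("A", -50, 0.5, 1), list("B", -60, 0.5, 1))
  expect_equal(rank_representations(gap)$optimal, "A")
  expect_match(rank_representations(gap)$rationale[["B"]], "evidence")
})

test_that("shifting every evidence by a constant leaves selection unchanged", {
  base <- ranked_input(list("a", -50, 1, 10), list("b", -52, 1, 1),
                       list("c", -60, 1, 1))
  shifted <- base
  shifted$mean_logZ <- shifted$mean_logZ + 1234.5
  r1 <- rank_representations(base)
  r2 <- rank_representations(shifted)
  expect_identical(r1$optimal, r2$optimal)
  expect_identical(r1$efficient_set, r2$efficient_set)
  expect_identical(r1$evidence_ranking, r2$evidence_ranking)
})

toy_factory <- function(label, topology, config, moves) {
  # evidence depends on the label so candidates are distinguishable
  mu <- 5 + as.numeric(label) / 100
  uniform_scorer(function(x) -(x - mu)^2 / 2, 0, 10)
}

test_that("toy orchestration is deterministic across repeat calls", {
  chains <- data.frame(chain_id = "A", length = 30)
  xl <- data.frame(protein1 = "A", residue1 = c(1, 5), protein2 = "A",
                   residue2 = c(20, 28))
  args <- list(chains, xl, candidates = c(5, 10), n_runs = 3, seed = 9,
               ns = ns_config(n_live = 15, max_iterations = 60),
               scorer_factory = toy_factory)
  f1 <- do.call(run_candidates, args)
  f2 <- do.call(run_candidates, args)
  # everything except wall-clock timing must reproduce exactly
  keep <- setdiff(names(f1$collated), "mean_per_step_time")
  expect_equal(f1$collated[keep], f2$collated[keep])
  expect_identical(
    lapply(f1$runs, function(rr) lapply(rr, `[[`, "dead_log_likelihoods")),
    lapply(f2$runs, function(rr) lapply(rr, `[[`, "dead_log_likelihoods")))
  expect_equal(f1$collated$n_successful_runs, c(3L, 3L))
  expect_true(all(f1$collated$sem_logZ >= 0))
})

test_that("results are identical for any worker count", {
  chains <- data.frame(chain_id = "A", length = 30)
  xl <- data.frame(protein1 = "A", residue1 = c(1, 5), protein2 = "A",
                   residue2 = c(20, 28))
  args <- list(chains, xl, candidates = c(5, 10), n_runs = 2, seed = 13,
               ns = ns_config(n_live = 10, max_iterations = 40),
               scorer_factory = toy_factory)
  serial <- do.call(run_candidates, c(args, workers = 1L))
  forked <- do.call(run_candidates, c(args, workers = 2L))
  keep <- setdiff(names(serial$collated), "mean_per_step_time")
  expect_equal(serial$collated[keep], forked$collated[keep])
})

test_that("failed runs are relaunched with fresh seeds", {
  counter <- new.env()
  counter$calls <- 0L
  flaky_factory <- function(label, topology, config, moves) {
    list(sample_prior = function() {
      counter$calls <- counter$calls + 1L
      # exhaust every retry of the first run's first live point
      if (counter$calls <= 3L) stop("sampler hiccup")
      stats::runif(1)
    },
    log_likelihood = function(s) -s^2)
  }
  out <- run_candidates(data.frame(chain_id = "A", length = 10),
                        data.frame(protein1 = "A", residue1 = 1,
                                   protein2 = "A", residue2 = 9),
                        candidates = 5, n_runs = 2, seed = 1,
                        ns = ns_config(n_live = 5, max_iterations = 10,
                                       max_attempts = 3),
                        scorer_factory = flaky_factory)
  expect_equal(out$collated$n_successful_runs, 2L)
  expect_false(out$collated$failed)
})

test_that("robustness needs at least two repartitions and handles no data", {
  chains <- data.frame(chain_id = "A", length = 20)
  xl <- data.frame(protein1 = "A", residue1 = c(1, 3, 5, 7),
                   protein2 = "A", residue2 = c(10, 12, 14, 16))
  expect_error(prior_robustness(chains, xl, candidates = 5,
                                n_repartitions = 1), "n_repartitions")

  # with no crosslinks the likelihood is identically zero: every split
  # must return log Z = 0 exactly
  suppressWarnings(
    rob0 <- prior_robustness(chains, xl[0, ], candidates = c(4, 10),
                             n_repartitions = 2, seed = 3, n_runs = 2,
                             moves = move_set(n_steps_per_sample = 5),
                             ns = ns_config(n_live = 5, max_iterations = 10,
                                            max_attempts = 3,
                                            max_consecutive_failures = 2,
                                            max_plateau_hits = 3)))
  expect_true(all(rob0$table$mean_logZ == 0))
})

test_that("configuration files drive the full fit", {
  dir <- withr::local_tempdir()
  chains <- data.frame(chain_id = c("A", "B"), length = c(30, 30))
  ref <- generate_reference_assembly(chains, seed = 5)
  xl <- simulate_crosslinks(ref, 12, seed = 6)
  write_topology(chains, file.path(dir, "topology.tsv"))
  write_crosslinks(xl, file.path(dir, "crosslinks.csv"))
  yaml::write_yaml(list(topology = "topology.tsv",
                        crosslinks = "crosslinks.csv",
                        candidates = c(10, 30), n_runs = 2, seed = 4,
                        moves = list(n_steps_per_sample = 10),
                        ns = list(n_live = 6, max_iterations = 12,
                                  max_attempts = 4,
                                  max_consecutive_failures = 3,
                                  max_plateau_hits = 4)),
                   file.path(dir, "config.yaml"))
  fit <- nsrep_from_config(file.path(dir, "config.yaml"))
  expect_s3_class(fit, "nsrep")
  expect_equal(fit$collated$label, c("10", "30"))
  expect_gt(length(fit$selection$optimal), 0)

  paths <- write_nsrep(fit, file.path(dir, "out"))
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(back$mean_logZ, fit$collated$mean_logZ, tolerance = 1e-12)
})
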