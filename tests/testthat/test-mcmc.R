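all_missing_matrix <- function(taxa, ncols = 40) {
  x <- matrix(NA_integer_, length(taxa), ncols,
              dimnames = list(taxa, NULL))
  supermatrix(x, data.frame(gene_id = "g1", start = 0, end = ncols))
}

test_that("identical seed and config reproduce the sample sequence", {
  set.seed(99)  # must not influence the seeded sampler
  m <- random_matrix(paste0("t", 1:4), 30, miss = 0.1)
  cfg <- mcmc_config(n_profiles = 2, n_iterations = 40,
                     burnin_fraction = 0.25, n_chains = 2, seed = 12)
  a <- mcmc_run(m, cfg)
  set.seed(1234)
  b <- mcmc_run(m, cfg)
  expect_identical(lapply(a[[1]], `[[`, "lnL"), lapply(b[[1]], `[[`, "lnL"))
  expect_identical(lapply(a[[2]], `[[`, "tree"), lapply(b[[2]], `[[`, "tree"))
  # chains differ from each other
  expect_false(identical(lapply(a[[1]], `[[`, "lnL"),
                         lapply(a[[2]], `[[`, "lnL")))
})

test_that("data-free sampling recovers the priors (small run)", {
  m <- all_missing_matrix(paste0("t", 1:4))
  cfg <- mcmc_config(n_profiles = 2, n_iterations = 3000,
                     burnin_fraction = 0.1, sample_thinning = 2,
                     n_chains = 1, seed = 31)
  ch <- mcmc_run(m, cfg)[[1]]
  bl <- unlist(lapply(ch, function(s) s$tree$edge.length))
  expect_lt(abs(mean(bl) - 0.1), 0.015)
  tops <- vapply(ch, function(s) tree_splits(s$tree), character(1))
  frac <- table(factor(tops, levels = c("t2|t3", "t2|t4", "t3|t4"))) /
    length(tops)
  # batch-means Monte-Carlo sigma (samples are autocorrelated)
  bm <- function(x, nb = 20) {
    b <- colMeans(matrix(x[seq_len(nb * (length(x) %/% nb))], ncol = nb))
    sd(b) / sqrt(nb)
  }
  for (k in 1:3) {
    sig <- bm(as.numeric(tops == names(frac)[k]))
    expect_lt(abs(frac[k] - 1 / 3), 3 * sig + 0.02)
  }
})

test_that("posterior supports count post-burn-in trees", {
  m <- random_matrix(paste0("t", 1:4), 25, miss = 0)
  cfg <- mcmc_config(n_profiles = 1, n_iterations = 100,
                     burnin_fraction = 0, n_chains = 1, seed = 3)
  ch <- mcmc_run(m, cfg)[[1]]
  expect_length(ch, 100)
  sup <- posterior_supports(ch, burnin_fraction = 0.5)
  manual <- split_frequencies(lapply(ch[51:100], `[[`, "tree"))
  expect_identical(sup$freq, manual$freq)
  expect_identical(sup$n_samples, 50L)
  # all-identical trees give unit posterior probability
  fixed <- lapply(1:5, function(i) ch[[1]])
  sup1 <- posterior_supports(fixed)
  expect_true(all(sup1$freq == 1))
  expect_error(posterior_supports(list(), 0), "no post-burn-in")
})

test_that("chains locked on different quartet topologies give MaxDiff 1", {
  # strongly informative data for topology A vs topology B as starting
  # points, topology moves disabled: each chain stays on its start
  m <- all_missing_matrix(paste0("t", 1:4), 10)
  cfg <- mcmc_config(n_profiles = 1, n_iterations = 60,
                     burnin_fraction = 0.5, n_chains = 2, seed = 8,
                     move_weights = c(allocation = 1, profile = 0,
                                      branch = 0, alpha = 1, topology = 0))
  chains <- mcmc_run(m, cfg)
  t1 <- posterior_supports(chains[[1]])
  t2 <- posterior_supports(chains[[2]])
  if (!identical(names(t1$freq), names(t2$freq))) {
    expect_equal(chain_compare(t1, t2)$max_diff, 1)
  } else succeed("chains initialized on the same topology")
  # two copies of one chain: (0, 0)
  same <- convergence_report(list(chains[[1]], chains[[1]]))
  expect_identical(same$max_diff, 0)
})

test_that("informative data concentrate the posterior near the ML tree", {
  set.seed(5)
  spec <- simulation_spec(n_taxa = 4, topology_mode = "newick",
                          newick = "((t1:0.15,t2:0.15):0.12,(t3:0.15,t4:0.15));",
                          n_genes = 2, gene_length_mean = 600,
                          gene_length_dispersion = 1e8, gene_rate_shape = 1e8,
                          alpha = 1e8, n_profiles = 1,
                          profile_concentration = 1e7,
                          target_completeness = 1, seed = 21)
  model <- substitution_model("poisson", alpha = 1)
  sim <- simulate_supermatrix(spec, model)
  cfg <- mcmc_config(n_profiles = 1, n_iterations = 400,
                     burnin_fraction = 0.5, n_chains = 1, seed = 9)
  ch <- mcmc_run(sim$matrix, cfg, model)[[1]]
  sup <- posterior_supports(ch)
  expect_gt(unname(sup$freq["t3|t4"]), 0.95)
  # posterior mean branch lengths near the ML optimum (K = 1)
  ml <- optimize_branch_lengths(sim$truth$true_tree, sim$matrix, model)
  pm_tl <- mean(vapply(ch, function(s) sum(s$tree$edge.length), 0))
  expect_lt(abs(pm_tl - sum(ml$tree$edge.length)) /
              sum(ml$tree$edge.length), 0.1)
})

test_that("Gibbs allocation finds well-separated profiles", {
  # two spiky, disjoint profiles: sites should be allocated to their own
  set.seed(6)
  p1 <- rep(1e-4, 20); p1[1:5] <- (1 - 15e-4) / 5
  p2 <- rep(1e-4, 20); p2[11:15] <- (1 - 15e-4) / 5
  profs <- profile_set(rbind(p1, p2))
  spec <- simulation_spec(n_taxa = 5, n_genes = 2, gene_length_mean = 150,
                          gene_length_dispersion = 1e8, gene_rate_shape = 1e8,
                          alpha = 1e8, n_profiles = 2,
                          target_completeness = 1, seed = 33)
  model <- substitution_model("poisson", alpha = 1, profiles = profs)
  sim <- simulate_supermatrix(spec, model)
  cfg <- mcmc_config(n_profiles = 2, n_iterations = 150,
                     burnin_fraction = 0.5, n_chains = 1, seed = 14)
  ch <- mcmc_run(sim$matrix, cfg, substitution_model("poisson", alpha = 1))[[1]]
  alloc <- ch[[length(ch)]]$site_allocations
  truth <- sim$truth$site_profile_assignments
  agree <- max(mean(alloc == truth), mean(alloc != truth))  # label switching
  expect_gt(agree, 0.8)
})

test_that("convergence of two chains on clean six-taxon data", {
  # a cleanly resolved 6-taxon tree: every internal branch long enough
  # that the posterior concentrates on the generating topology
  spec <- simulation_spec(
    n_taxa = 6, topology_mode = "newick",
    newick = "((t1:0.2,t2:0.2):0.25,(t3:0.2,t4:0.2):0.25,(t5:0.2,t6:0.2):0.25);",
    n_genes = 3, gene_length_mean = 100, gene_length_dispersion = 1e8,
    gene_rate_shape = 1e8, n_profiles = 1, profile_concentration = 1e7,
    target_completeness = 1, seed = 51)
  model <- substitution_model("poisson", alpha = 1)
  sim <- simulate_supermatrix(spec, model)
  ok <- 0L; n_trials <- 5L
  for (i in seq_len(n_trials)) {
    cfg <- mcmc_config(n_profiles = 1, n_iterations = 200,
                       burnin_fraction = 0.5, n_chains = 2, seed = 60 + i)
    cr <- convergence_report(mcmc_run(sim$matrix, cfg, model))
    expect_lte(cr$mean_diff, cr$max_diff)
    if (cr$max_diff < 0.1) ok <- ok + 1L
  }
  expect_gte(ok, n_trials - 1L)
})
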