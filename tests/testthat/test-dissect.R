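# build a supermatrix whose genes evolved at known rate multipliers by
# simulating on rate-scaled copies of one tree
sim_genes_at_rates <- function(mults, seed, n_taxa = 5, len = 100) {
  base <- simulation_spec(n_taxa = n_taxa, seed = seed)
  tr <- build_tree(base)
  model <- substitution_model("poisson", alpha = 1)
  genes <- list()
  for (i in seq_along(mults)) {
    sc <- tr
    sc$edge.length <- sc$edge.length * mults[i]
    spec <- simulation_spec(n_taxa = n_taxa, topology_mode = "newick",
                            newick = ape::write.tree(sc), n_genes = 1,
                            gene_length_mean = len,
                            gene_length_dispersion = 1e8,
                            gene_rate_shape = 1e8, alpha = 1e8,
                            n_profiles = 1, profile_concentration = 1e7,
                            target_completeness = 1, seed = seed * 131 + i)
    sim <- simulate_supermatrix(spec, model)
    ch <- phylosect:::as_char_matrix(sim$matrix)
    genes[[paste0("g", i)]] <- apply(ch, 1, paste0, collapse = "")
  }
  list(matrix = concatenate(genes), tree = ape::unroot(tr))
}

test_that("relative rates average exactly one and rank true multipliers", {
  model <- substitution_model("poisson", alpha = 1)
  hits <- 0L; n_rep <- 100L
  for (r in seq_len(n_rep)) {
    fx <- sim_genes_at_rates(c(0.5, 1, 2), seed = 1000 + r)
    rt <- estimate_gene_rates(fx$matrix, fx$tree, model, max_sweeps = 2)
    expect_equal(mean(rt$table$relative_rate), 1, tolerance = 1e-9)
    if (identical(order(rt$table$relative_rate), 1:3)) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.95)
})

test_that("equal-rate genes are estimated near rate 1", {
  model <- substitution_model("poisson", alpha = 1)
  rates <- unlist(lapply(1:25, function(r) {
    fx <- sim_genes_at_rates(c(1, 1, 1), seed = 4000 + r)
    estimate_gene_rates(fx$matrix, fx$tree, model,
                        max_sweeps = 2)$table$relative_rate
  }))
  # replicate-based CI: every rate within the empirical 6-sd band around 1
  expect_lt(abs(mean(rates) - 1), 3 * sd(rates) / sqrt(length(rates)))
  expect_true(all(abs(rates - 1) < 6 * sd(rates)))
})

test_that("genes with too few data-bearing taxa are excluded with warning", {
  fx <- sim_genes_at_rates(c(1, 1), seed = 7, n_taxa = 5, len = 40)
  # blank out gene 2 for all but 2 taxa
  p <- fx$matrix$partitions
  fx$matrix$x[3:5, (p$start[2] + 1):p$end[2]] <- NA_integer_
  model <- substitution_model("poisson", alpha = 1)
  expect_warning(rt <- estimate_gene_rates(fx$matrix, fx$tree, model,
                                           max_sweeps = 2), "unestimable")
  expect_equal(rt$excluded, "g2")
  expect_equal(rt$table$gene_id, "g1")
})

test_that("quartile assignment: sorting, sizes, monotone rates, permutation", {
  set.seed(77)
  x <- matrix(sample.int(20, 8 * 800, replace = TRUE), 8, 800,
              dimnames = list(paste0("t", 1:8), NULL))
  sm <- supermatrix(x, data.frame(gene_id = paste0("g", 1:8),
                                  start = seq(0, 700, 100),
                                  end = seq(100, 800, 100)))
  rt <- rate_table(paste0("g", 1:8), c(5, 3, 8, 1, 7, 2, 6, 4))
  qs <- partition_quartiles(sm, rt)
  # 8 equal-length genes, distinct rates: Q1 holds the two slowest
  expect_equal(sort(qs$genes$Q1), c("g4", "g6"))
  expect_equal(vapply(qs$genes, length, integer(1)),
               c(Q1 = 2L, Q2 = 2L, Q3 = 2L, Q4 = 2L))
  # gene sets partition the input
  expect_setequal(unlist(qs$genes), paste0("g", 1:8))
  # monotone non-decreasing quartile rates
  expect_true(all(diff(qs$summary$relative_rate) >= 0))
  # sizes within one max gene length of total/4, by exhaustive recount
  lens <- vapply(qs$matrices, function(m) ncol(m$x), integer(1))
  expect_true(all(abs(lens - 200) <= 100))
  expect_equal(sum(lens), 800L)

  # permuting the gene input order changes nothing
  perm <- c(5, 1, 8, 3, 2, 7, 4, 6)
  cols <- unlist(lapply(perm, function(i) (100 * (i - 1)):(100 * i - 1)))
  sm2 <- slice_columns(sm, cols)
  qs2 <- partition_quartiles(sm2, rt)
  for (k in 1:4) expect_setequal(qs2$genes[[k]], qs$genes[[k]])

  expect_error(suppressWarnings(partition_quartiles(sm, rate_table("g1", 1))),
               "4 rated genes")
})

test_that("quartile summaries report column-weighted rates and missingness", {
  set.seed(78)
  x <- matrix(sample.int(20, 4 * 100, replace = TRUE), 4, 100,
              dimnames = list(paste0("t", 1:4), NULL))
  x[1, 1:10] <- NA
  sm <- supermatrix(x, data.frame(gene_id = paste0("g", 1:4),
                                  start = c(0, 25, 50, 75),
                                  end = c(25, 50, 75, 100)))
  rt <- rate_table(paste0("g", 1:4), c(1, 2, 3, 4))
  qs <- partition_quartiles(sm, rt)
  expect_equal(qs$summary$pct_missing[1], 100 * 10 / 100)
  expect_equal(qs$summary$relative_rate[1],
               rt$table$relative_rate[1], tolerance = 1e-12)
})

test_that("identical quartile data give identical ML trees; report matches brute force", {
  set.seed(79)
  sim <- simulate_supermatrix(
    simulation_spec(n_taxa = 5, n_genes = 4, gene_length_mean = 60,
                    gene_length_dispersion = 1e8, n_profiles = 1,
                    profile_concentration = 1e7, target_completeness = 1,
                    seed = 41))
  ch <- phylosect:::as_char_matrix(sim$matrix)
  one_gene <- apply(ch[, 1:60], 1, paste0, collapse = "")
  same <- concatenate(list(g1 = one_gene, g2 = one_gene, g3 = one_gene,
                           g4 = one_gene))
  rt <- rate_table(paste0("g", 1:4), c(1, 1.0001, 1.0002, 1.0003))
  model <- substitution_model("poisson", alpha = 1)
  res <- dissection_experiment(same, rt, model, method = "ml",
                               max_sweeps = 2)
  for (k in 2:4)
    expect_equal(sort(tree_splits(res$trees[[k]])),
                 sort(tree_splits(res$trees$Q1)))
  expect_equal(nrow(res$report), 0L)

  # a run with heterogeneous quartiles: the report lists exactly the
  # symmetric-difference splits of every pair
  sim2 <- simulate_supermatrix(
    simulation_spec(n_taxa = 6, n_genes = 8, gene_length_mean = 50,
                    n_profiles = 2, target_completeness = 1, seed = 42))
  rt2 <- rate_table(sim2$matrix$partitions$gene_id,
                    unname(sim2$truth$gene_rates))
  res2 <- dissection_experiment(sim2$matrix, rt2, model, max_sweeps = 2)
  for (a in 1:3) for (b in (a + 1):4) {
    sa <- tree_splits(res2$trees[[a]]); sb <- tree_splits(res2$trees[[b]])
    want <- sort(union(setdiff(sa, sb), setdiff(sb, sa)))
    got <- sort(res2$report$split[res2$report$pair == paste0("Q", a, "-Q", b)])
    expect_equal(got, want)
  }
})
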