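test_that("identical sequences drive branch lengths to the floor", {
  tr <- ape::read.tree(text = "((A:0.3,B:0.2):0.1,(C:0.4,D:0.2):0.3);")
  sm <- concatenate(list(g1 = c(A = "ARNDCQEG", B = "ARNDCQEG",
                                C = "ARNDCQEG", D = "ARNDCQEG")))
  m <- substitution_model("poisson", alpha = 1)
  fit <- optimize_branch_lengths(tr, sm, m)
  expect_true(all(fit$tree$edge.length <= 1e-8 + 1e-12))
  # lengths sit at the 1e-8 floor, not 0, so allow the tiny deficit
  expect_equal(fit$lnL, 8 * log(1 / 20), tolerance = 1e-6)
})

test_that("optimization never decreases the log-likelihood", {
  set.seed(21)
  for (i in 1:5) {
    tr <- ape::rtree(5, tip.label = paste0("t", 1:5))
    mat <- random_matrix(tr$tip.label, 40, miss = 0.2)
    m <- random_model(20, ncat = 2)
    start <- log_likelihood(tr, mat, m)
    fit <- optimize_branch_lengths(tr, mat, m, max_sweeps = 3)
    expect_gte(fit$lnL, start - 1e-9)
    expect_equal(fit$lnL, log_likelihood(fit$tree, mat, m), tolerance = 1e-9)
  }
})

test_that("two-taxon optimum matches the analytic two-state MLE", {
  # 2-state symmetric model: P(diff) = (1 - exp(-2t)) / 2 under unit
  # normalization, so t_hat = -log(1 - 2p) / 2 for difference fraction p
  ab <- c("0", "1")
  m <- substitution_model("poisson", alphabet = ab, alpha = 1,
                          n_categories = 1)
  n <- 200; ndiff <- 30
  x <- rbind(A = rep(c(1L, 1L), c(n - ndiff, ndiff)),
             B = rep(c(1L, 2L), c(n - ndiff, ndiff)))
  sm <- supermatrix(x, data.frame(gene_id = "g", start = 0, end = n),
                    alphabet = ab)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  fit <- optimize_branch_lengths(tr, sm, m)
  p <- ndiff / n
  expect_equal(sum(fit$tree$edge.length), -log(1 - 2 * p) / 2,
               tolerance = 1e-5)
})

test_that("NJ recovers an additive four-taxon metric exactly", {
  # hand-constructed additive distances on ((A,B),(C,D)) with branch
  # lengths A=.1 B=.2 C=.15 D=.25 internal=.05
  taxa <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  bl <- c(A = .1, B = .2, C = .15, D = .25); int <- .05
  D["A", "B"] <- D["B", "A"] <- bl["A"] + bl["B"]
  D["C", "D"] <- D["D", "C"] <- bl["C"] + bl["D"]
  for (i in c("A", "B")) for (j in c("C", "D"))
    D[i, j] <- D[j, i] <- bl[i] + bl[j] + int
  tr <- ape::nj(as.dist(D))
  expect_equal(sort(tree_splits(tr)), "C|D")
  expect_equal(sum(tr$edge.length), sum(bl) + int, tolerance = 1e-12)
})

test_that("nj_tree: three taxa, unique topology; order invariance", {
  set.seed(31)
  sim <- simulate_supermatrix(
    simulation_spec(n_taxa = 6, n_genes = 5, gene_length_mean = 60,
                    n_profiles = 2, target_completeness = 1, seed = 31))
  m <- substitution_model("poisson", alpha = 1)
  three <- sim$matrix
  three$x <- three$x[1:3, , drop = FALSE]
  tr3 <- nj_tree(three, m)
  expect_equal(length(tr3$tip.label), 3L)

  full <- nj_tree(sim$matrix, m)
  perm <- sim$matrix
  ord <- c(4, 2, 6, 1, 3, 5)
  perm$x <- perm$x[ord, , drop = FALSE]
  tr_perm <- nj_tree(perm, m)
  expect_equal(sort(tree_splits(tr_perm)), sort(tree_splits(full)))
})

test_that("nj_tree names the offending pair on zero overlap", {
  x <- matrix(c(1L, 2L, 3L, NA, NA, NA,
                NA, NA, NA, 1L, 2L, 3L,
                1L, 1L, 1L, 1L, 1L, 1L), 3, 6, byrow = TRUE,
              dimnames = list(c("tA", "tB", "tC"), NULL))
  sm <- supermatrix(x, data.frame(gene_id = "g", start = 0, end = 6))
  expect_error(nj_tree(sm, substitution_model("poisson")), "tA.*tB")
})

test_that("NNI search recovers the generating 5-taxon topology from every start", {
  set.seed(41)
  spec <- simulation_spec(n_taxa = 5, topology_mode = "newick",
                          newick = "((t1:0.2,t2:0.2):0.15,(t3:0.2,t4:0.2):0.15,t5:0.3);",
                          n_genes = 2, gene_length_mean = 400,
                          gene_length_dispersion = 1e6, gene_rate_shape = 1e6,
                          n_profiles = 1, profile_concentration = 1e7,
                          target_completeness = 1, seed = 17)
  m <- substitution_model("poisson", alpha = 1)
  sim <- simulate_supermatrix(spec, m)
  truth_splits <- sort(tree_splits(sim$truth$true_tree))

  # exhaustive oracle over all 15 unrooted topologies
  all_tops <- phangorn::allTrees(5, rooted = FALSE,
                                 tip.label = paste0("t", 1:5))
  scores <- vapply(seq_along(all_tops), function(i) {
    tr <- all_tops[[i]]
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    optimize_branch_lengths(tr, sim$matrix, m, max_sweeps = 4)$lnL
  }, numeric(1))
  best_top <- all_tops[[which.max(scores)]]
  expect_equal(sort(tree_splits(best_top)), truth_splits)

  # greedy NNI reaches the same optimum from several random starts
  for (i in c(1, 6, 11)) {
    start <- all_tops[[i]]
    start$edge.length <- rep(0.1, nrow(start$edge))
    fit <- nni_search(start, sim$matrix, m, max_sweeps = 4)
    expect_equal(sort(tree_splits(fit$tree)), truth_splits)
    expect_equal(fit$lnL, max(scores), tolerance = 1e-3)
  }
})

test_that("NNI search result is invariant to consistent leaf relabeling", {
  set.seed(51)
  sim <- simulate_supermatrix(
    simulation_spec(n_taxa = 5, n_genes = 3, gene_length_mean = 80,
                    n_profiles = 1, profile_concentration = 1e7,
                    target_completeness = 1, seed = 3))
  m <- substitution_model("poisson", alpha = 1)
  fit <- nni_search(nj_tree(sim$matrix, m), sim$matrix, m, max_sweeps = 3)

  # permute the labels consistently in data and start tree
  perm <- setNames(paste0("t0", c(3, 5, 1, 2, 4)), taxa_of(sim$matrix))
  mat2 <- sim$matrix
  rownames(mat2$x) <- unname(perm[rownames(mat2$x)])
  start2 <- nj_tree(mat2, m)
  fit2 <- nni_search(start2, mat2, m, max_sweeps = 3)
  relabeled <- vapply(strsplit(sort(tree_splits(fit$tree)), "|",
                               fixed = TRUE),
                     function(s) paste(sort(unname(perm[s])), collapse = "|"),
                     character(1))
  # canonicalize relabeled splits against the new taxon universe
  relabeled <- vapply(relabeled, function(k)
    canonical_split(strsplit(k, "|", fixed = TRUE)[[1]],
                    unname(perm)), character(1))
  expect_setequal(unname(relabeled), tree_splits(fit2$tree))
})

test_that("NNI search is a fixed point at the maximum-likelihood tree", {
  set.seed(61)
  sim <- simulate_supermatrix(
    simulation_spec(n_taxa = 4, topology_mode = "newick",
                    newick = "((t1:0.2,t2:0.2):0.2,(t3:0.2,t4:0.2));",
                    n_genes = 2, gene_length_mean = 150,
                    gene_length_dispersion = 1e6, gene_rate_shape = 1e6,
                    n_profiles = 1, profile_concentration = 1e7,
                    target_completeness = 1, seed = 9))
  m <- substitution_model("poisson", alpha = 1)
  fit <- nni_search(sim$truth$true_tree, sim$matrix, m)
  expect_equal(sort(tree_splits(fit$tree)),
               sort(tree_splits(sim$truth$true_tree)))
})
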