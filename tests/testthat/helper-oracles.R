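# Independent reference implementations used as oracles. They deliberately
# share no code with the package internals they check.

# Brute-force tree likelihood by exhaustive enumeration of internal-node
# states (vectorized over the assignment grid). Missing tips are handled by
# omitting their edge factor (row sums of P are 1).
oracle_loglik <- function(tree, matrix, model) {
  tr <- stats::reorder(tree, "postorder")
  edges <- tr$edge
  len <- pmax(tr$edge.length, 0)
  A <- length(model$alphabet)
  rm_ <- rate_matrix(model)
  g <- discrete_gamma_rates(model$alpha, model$n_categories)
  x <- matrix$x[match(tr$tip.label, rownames(matrix$x)), , drop = FALSE]
  ntip <- nrow(x)
  nnode_tot <- max(edges)
  internals <- setdiff(seq_len(nnode_tot), seq_len(ntip))
  root <- edges[nrow(edges), 1]
  grid <- as.matrix(expand.grid(rep(list(seq_len(A)), length(internals))))
  node_col <- function(states_tips, node, site) {
    if (node <= ntip) rep(states_tips[node, site], nrow(grid))
    else grid[, match(node, internals)]
  }
  Pk <- lapply(seq_along(g$rates), function(k)
    lapply(seq_len(nrow(edges)), function(e)
      transition_probabilities(rm_, len[e] * g$rates[k])))
  total <- 0
  for (site in seq_len(ncol(x))) {
    lik <- 0
    for (k in seq_along(g$rates)) {
      P <- Pk[[k]]
      f <- rm_$pi[node_col(x, root, site)]
      for (e in seq_len(nrow(edges))) {
        b_states <- node_col(x, edges[e, 2], site)
        if (anyNA(b_states)) next                  # missing tip marginalizes
        a_states <- node_col(x, edges[e, 1], site)
        f <- f * P[[e]][cbind(a_states, b_states)]
      }
      lik <- lik + g$weights[k] * sum(f)
    }
    total <- total + log(lik)
  }
  total
}

# Quadratic reference DP for Smith-Waterman with affine gaps
# (gap of length L costs open + L * extend).
oracle_sw <- function(q, t, smat, open, extend) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  M <- X <- Y <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                          Y[i - 1, j - 1]) + smat[qs[i - 1], ts[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

# Exhaustive Dollo minimization: smallest set of loss branches (below the
# single gain at the MRCA of present taxa) explaining the observed states.
# Returns the minimal loss count, or NA if inconsistent.
oracle_dollo_count <- function(tree, undetected) {
  tree <- ensure_node_labels(tree)
  present <- names(undetected)[!undetected]
  if (length(present) == 0L) return(0L)
  origin <- if (length(present) == 1L) match(present, tree$tip.label)
            else ape::getMRCA(tree, present)
  nt <- length(tree$tip.label)
  clade_tips <- if (origin <= nt) tree$tip.label[origin]
                else tree$tip.label[phangorn::Descendants(tree, origin, "tips")[[1]]]
  if (any(!undetected[setdiff(names(undetected), clade_tips)])) stop("bad origin")
  # candidate branches: those whose below-tip set lies within the clade
  cand <- which(vapply(seq_len(nrow(tree$edge)), function(e)
    all(tips_below_edge(tree, e) %in% clade_tips), logical(1)))
  inc <- vapply(cand, function(e) clade_tips %in% tips_below_edge(tree, e),
                logical(length(clade_tips)))   # tips x branches
  target <- unname(undetected[clade_tips])
  for (k in 0:length(cand)) {
    if (k == 0L) {
      if (!any(target)) return(0L)
      next
    }
    for (pick in utils::combn(length(cand), k, simplify = FALSE)) {
      pred <- rowSums(inc[, pick, drop = FALSE]) > 0
      if (identical(unname(pred), target)) return(k)
    }
  }
  NA_integer_
}

# random reversible model over a random alphabet size
random_model <- function(A = 20, ncat = sample(1:2, 1),
                         alphabet = AA_ALPHABET[seq_len(A)]) {
  r <- matrix(0, A, A)
  r[upper.tri(r)] <- runif(A * (A - 1) / 2, 0.2, 2)
  r <- r + t(r)
  pi <- rgamma(A, 2, 1); pi <- pi / sum(pi)
  substitution_model(r, pi, alpha = runif(1, 0.3, 3), n_categories = ncat,
                     alphabet = alphabet)
}

# small random supermatrix over a model's alphabet with missing cells
random_matrix <- function(taxa, ncols, A = 20, miss = 0.1) {
  x <- matrix(sample.int(A, length(taxa) * ncols, replace = TRUE),
              length(taxa), ncols, dimnames = list(taxa, NULL))
  x[matrix(runif(length(x)) < miss, nrow(x), ncol(x))] <- NA_integer_
  # keep at least one observed cell per column
  for (j in which(colSums(!is.na(x)) == 0L)) x[1, j] <- 1L
  supermatrix(x, data.frame(gene_id = "g1", start = 0, end = ncols),
              alphabet = AA_ALPHABET[seq_len(A)])
}
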