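## Likelihood engine: pattern compression + pruning core glue.

# postorder edge list of an ape tree, 0-based
tree_postorder <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  len <- tr$edge.length
  if (is.null(len)) stop("tree lacks branch lengths")
  list(edges = tr$edge - 1L, len = pmax(len, 0), tree = tr)
}

# compress alignment columns (integer matrix, NA = missing) to site patterns
compress_patterns <- function(x) {
  x[is.na(x)] <- -1L
  keys <- do.call(paste, c(as.data.frame(t(x)), list(sep = ",")))
  u <- !duplicated(keys)
  index <- match(keys, keys[u])
  list(pat = x[, u, drop = FALSE], weights = tabulate(index, sum(u)),
       index = index)
}

# per-pattern log-likelihood for one set of root frequencies
# tipmat rows must be ordered as tree$tip.label
plik_patterns <- function(po, tipmat, pi, Q, rates, wk) {
  ed <- edecomp(Q, pi)
  nedge <- nrow(po$edges)
  ncat <- length(rates)
  A <- length(pi)
  P <- array(0, c(A, A, nedge * ncat))
  for (e in seq_len(nedge))
    for (k in seq_len(ncat))
      P[, , (e - 1L) * ncat + k] <- pmat_from_edecomp(ed, po$len[e] * rates[k])
  plik_patterns_cpp(po$edges, P, tipmat, pi, wk)
}

# order matrix rows to the tree's tip order; error on mismatch
tipmat_for_tree <- function(matrix, tree) {
  taxa <- taxa_of(matrix)
  if (!setequal(taxa, tree$tip.label) || length(taxa) != length(tree$tip.label))
    stop("tree leaves and matrix taxa do not match")
  x <- matrix$x[match(tree$tip.label, taxa), , drop = FALSE] - 1L
  x[is.na(x)] <- -1L
  x
}

#' Log-likelihood of a supermatrix on a tree
#'
#' Felsenstein pruning with discrete-gamma rate categories and optional
#' site-heterogeneous equilibrium-frequency profiles. Missing states
#' contribute all-ones partials (a column missing in every taxon adds
#' exactly 0). Per-node rescaling keeps the computation finite for
#' arbitrarily wide matrices.
#'
#' With `site_profile_map`, each column uses its assigned profile's
#' frequencies; with profiles in the model but no map, each site averages
#' over profiles with the mixture weights; with neither, the model's single
#' frequency vector is used.
#'
#' @param tree an `ape::phylo` tree with branch lengths, leaves = taxa.
#' @param matrix a [supermatrix()].
#' @param model a [substitution_model()].
#' @param site_profile_map optional integer vector, one 1-based profile
#'   index per column.
#' @param per_site return the per-column log-likelihood vector instead of
#'   the sum?
#' @return the total log-likelihood (or per-column vector).
#' @export
log_likelihood <- function(tree, matrix, model, site_profile_map = NULL,
                           per_site = FALSE) {
  stopifnot(inherits(matrix, "supermatrix"),
            inherits(model, "substitution_model"))
  tipmat <- tipmat_for_tree(matrix, tree)
  po <- tree_postorder(tree)
  tipmat <- tipmat[match(po$tree$tip.label, tree$tip.label), , drop = FALSE]
  g <- discrete_gamma_rates(model$alpha, model$n_categories)
  nc <- ncol(tipmat)

  site_ll <- numeric(nc)
  if (!is.null(site_profile_map)) {
    if (is.null(model$profiles)) stop("site_profile_map given but model carries no profiles")
    stopifnot(length(site_profile_map) == nc)
    for (c_idx in sort(unique(site_profile_map))) {
      cols <- which(site_profile_map == c_idx)
      cp <- compress_patterns(tipmat[, cols, drop = FALSE])
      rm_ <- rate_matrix(model, profile_index = c_idx)
      ll <- plik_patterns(po, cp$pat, rm_$pi, rm_$Q, g$rates, g$weights)
      site_ll[cols] <- ll[cp$index]
    }
  } else if (!is.null(model$profiles)) {
    K <- nrow(model$profiles$profiles)
    w <- model$profiles$weights
    cp <- compress_patterns(tipmat)
    llk <- matrix(0, K, length(cp$weights))
    for (c_idx in seq_len(K)) {
      rm_ <- rate_matrix(model, profile_index = c_idx)
      llk[c_idx, ] <- plik_patterns(po, cp$pat, rm_$pi, rm_$Q, g$rates, g$weights)
    }
    if (K == 1L) {
      ll <- llk[1L, ] + log(w[1L])
    } else {
      mx <- apply(llk, 2, max)
      ll <- mx + log(colSums(w * exp(sweep(llk, 2, mx))))
    }
    site_ll <- ll[cp$index]
  } else {
    cp <- compress_patterns(tipmat)
    rm_ <- rate_matrix(model)
    ll <- plik_patterns(po, cp$pat, rm_$pi, rm_$Q, g$rates, g$weights)
    site_ll <- ll[cp$index]
  }
  if (per_site) site_ll else sum(site_ll)
}
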