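## Branch-length optimization, NNI search, NJ starting trees.

# Precompiled likelihood-as-function-of-branch-lengths for a fixed topology.
# Pattern compression and eigendecompositions are done once; each call
# rebuilds only the transition matrices.
lnl_engine <- function(po, tipmat, model, site_profile_map = NULL) {
  g <- discrete_gamma_rates(model$alpha, model$n_categories)
  nedge <- nrow(po$edges)
  ncat <- length(g$rates)
  A <- length(model$alphabet)
  build_P <- function(ed, len) {
    P <- array(0, c(A, A, nedge * ncat))
    for (e in seq_len(nedge))
      for (k in seq_len(ncat))
        P[, , (e - 1L) * ncat + k] <-
          pmat_from_edecomp(ed, len[e] * g$rates[k])
    P
  }
  if (!is.null(site_profile_map)) {
    idx <- sort(unique(site_profile_map))
    groups <- lapply(idx, function(c_idx) {
      rm_ <- rate_matrix(model, profile_index = c_idx)
      cp <- compress_patterns(tipmat[, site_profile_map == c_idx, drop = FALSE])
      list(ed = edecomp(rm_$Q, rm_$pi), pi = rm_$pi,
           pat = cp$pat, w = cp$weights)
    })
    function(len) {
      tot <- 0
      for (grp in groups) {
        ll <- plik_patterns_cpp(po$edges, build_P(grp$ed, len), grp$pat,
                                grp$pi, g$weights)
        tot <- tot + sum(grp$w * ll)
      }
      tot
    }
  } else if (!is.null(model$profiles)) {
    K <- nrow(model$profiles$profiles)
    wp <- model$profiles$weights
    cp <- compress_patterns(tipmat)
    eds <- lapply(seq_len(K), function(c_idx) {
      rm_ <- rate_matrix(model, profile_index = c_idx)
      list(ed = edecomp(rm_$Q, rm_$pi), pi = rm_$pi)
    })
    function(len) {
      llk <- vapply(eds, function(z)
        as.numeric(plik_patterns_cpp(po$edges, build_P(z$ed, len), cp$pat,
                                     z$pi, g$weights)),
        numeric(length(cp$weights)))
      llk <- matrix(llk, K, length(cp$weights), byrow = TRUE)
      if (K == 1L) {
        ll <- llk[1L, ] + log(wp[1L])
      } else {
        mx <- apply(llk, 2, max)
        ll <- mx + log(colSums(wp * exp(sweep(llk, 2, mx))))
      }
      sum(cp$weights * ll)
    }
  } else {
    rm_ <- rate_matrix(model)
    ed <- edecomp(rm_$Q, rm_$pi)
    cp <- compress_patterns(tipmat)
    function(len) {
      ll <- plik_patterns_cpp(po$edges, build_P(ed, len), cp$pat, rm_$pi,
                              g$weights)
      sum(cp$weights * ll)
    }
  }
}

#' Optimize branch lengths on a fixed topology
#'
#' Iterative per-branch univariate (Brent) optimization, sweeping over all
#' branches until the log-likelihood improves by less than `tol`. Flat
#' profiles are resolved toward the smaller branch length; lengths are
#' floored at `bl_floor` to keep the eigendecomposition-based transition
#' matrices well conditioned.
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance on lnL (and branch lengths).
#' @param bl_floor smallest admissible branch length.
#' @param bl_max largest admissible branch length.
#' @param max_sweeps cap on full sweeps.
#' @return list with `tree` (optimized lengths) and `lnL`; the returned
#'   lnL is never below the starting one.
#' @export
optimize_branch_lengths <- function(tree, matrix, model,
                                    site_profile_map = NULL, tol = 1e-6,
                                    bl_floor = 1e-8, bl_max = 20,
                                    max_sweeps = 50L) {
  tipmat <- tipmat_for_tree(matrix, tree)
  po <- tree_postorder(tree)
  tipmat <- tipmat[match(po$tree$tip.label, tree$tip.label), , drop = FALSE]
  if (is.null(site_profile_map) && is.null(model$profiles)) {
    # fast path: exact per-branch smoothing with two-sided partials in C++
    cp <- compress_patterns(tipmat)
    rm_ <- rate_matrix(model)
    ed <- edecomp(rm_$Q, rm_$pi)
    g <- discrete_gamma_rates(model$alpha, model$n_categories)
    res <- optimize_branches_cpp(po$edges, pmax(po$len, bl_floor), ed$L,
                                 ed$R, ed$lambda, rm_$pi, cp$pat,
                                 cp$weights, g$rates, g$weights, tol,
                                 max_sweeps, bl_floor, bl_max)
    out <- po$tree
    out$edge.length <- as.numeric(res$t)
    return(list(tree = out, lnL = res$lnL))
  }
  f <- lnl_engine(po, tipmat, model, site_profile_map)
  len <- pmax(po$len, bl_floor)
  cur <- f(len)
  for (sweep_i in seq_len(max_sweeps)) {
    prev <- cur
    for (e in seq_along(len)) {
      opt <- optimize(function(t) f(replace(len, e, t)),
                      c(bl_floor, bl_max), maximum = TRUE, tol = tol)
      t_new <- opt$maximum
      l_new <- opt$objective
      if (t_new < 1e-3) {             # boundary check; ties go to the floor
        l_floor <- f(replace(len, e, bl_floor))
        if (l_floor >= l_new - 1e-9) { t_new <- bl_floor; l_new <- l_floor }
      }
      if (l_new >= cur) { len[e] <- t_new; cur <- l_new }
    }
    if (cur - prev < tol) break
  }
  out <- po$tree
  out$edge.length <- len
  list(tree = out, lnL = cur)
}

#' Greedy NNI hill-climbing tree search
#'
#' Starting from `start`, repeatedly evaluates all nearest-neighbour
#' interchanges (with branch-length re-optimization) and moves to the best
#' neighbour until none improves the log-likelihood by more than `tol`.
#'
#' @inheritParams optimize_branch_lengths
#' @param start starting tree (>= 4 leaves); it is unrooted internally.
#' @return list with `tree` and `lnL` (`>=` the optimized start lnL).
#' @export
nni_search <- function(start, matrix, model, site_profile_map = NULL,
                       tol = 1e-6, ...) {
  if (length(start$tip.label) < 4L) stop("NNI search needs >= 4 leaves")
  tr <- ape::unroot(start)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  cur <- optimize_branch_lengths(tr, matrix, model, site_profile_map,
                                 tol = tol, ...)
  repeat {
    nbs <- phangorn::nni(cur$tree)
    best <- NULL
    for (i in seq_along(nbs)) {
      nb <- nbs[[i]]        # [[ restores compressed multiPhylo tip labels
      if (is.null(nb$edge.length)) nb$edge.length <- rep(0.1, nrow(nb$edge))
      # cheap screen: one smoothing sweep ranks the neighbourhood
      cand <- optimize_branch_lengths(nb, matrix, model, site_profile_map,
                                      tol = tol, max_sweeps = 1L)
      if (is.null(best) || cand$lnL > best$lnL) best <- cand
    }
    if (is.null(best)) break
    best <- optimize_branch_lengths(best$tree, matrix, model,
                                    site_profile_map, tol = tol, ...)
    if (best$lnL > cur$lnL + tol) cur <- best else break
  }
  cur
}

#' Neighbour-joining starting tree from pairwise ML distances
#'
#' Each pairwise distance is the two-taxon maximum-likelihood branch length
#' under the model's gamma mixture, restricted to columns where both taxa
#' have data. The distance matrix is handed to standard neighbour joining
#' (`ape::nj`); negative NJ branch lengths are clamped to 0.
#'
#' @inheritParams log_likelihood
#' @param d_max cap on pairwise distances.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(matrix, model, d_max = 20) {
  taxa <- taxa_of(matrix)
  n <- length(taxa)
  if (n < 3L) stop("NJ needs >= 3 taxa")
  g <- discrete_gamma_rates(model$alpha, model$n_categories)
  rm_ <- rate_matrix(model)
  ed <- edecomp(rm_$Q, rm_$pi)
  A <- length(model$alphabet)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    xi <- matrix$x[i, ]; xj <- matrix$x[j, ]
    ok <- !is.na(xi) & !is.na(xj)
    if (!any(ok))
      stop("no overlapping columns for taxa ", taxa[i], " and ", taxa[j])
    N <- table(factor(xi[ok], levels = seq_len(A)),
               factor(xj[ok], levels = seq_len(A)))
    N <- unclass(N)
    f <- function(t) {
      M <- 0
      for (k in seq_along(g$rates))
        M <- M + g$weights[k] * pmat_from_edecomp(ed, t * g$rates[k])
      sum(N * log(pmax(rm_$pi * M, 1e-300)))
    }
    opt <- optimize(f, c(1e-8, d_max), maximum = TRUE, tol = 1e-7)
    # identical rows: the optimum sits at the lower boundary
    d <- if (f(1e-8) >= opt$objective) 0 else opt$maximum
    D[i, j] <- D[j, i] <- d
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}
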